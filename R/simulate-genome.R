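#' Generate a synthetic annotated genome with ground truth
#'
#' Builds contigs as alternating intergenic regions and non-overlapping
#' genes, assigns defense / housekeeping / other roles from the spec's
#' mixture, plants defense islands (contiguous non-housekeeping runs with
#' at least one defense gene, flanked by housekeeping genes) and intergenic
#' RNA motifs, and returns truth tables sufficient to score every
#' downstream stage. All coordinates are 0-based half-open.
#'
#' @param spec A [genome_spec()].
#' @return List with tibbles `genome` (`contig`, `seq`), `genes` (`contig`,
#'   `gene_id`, `start`, `end`, `strand`, `role`, `protein`), `islands`
#'   (truth table of maximal defense islands), `motifs` (planted motif
#'   coordinates), `igrs` (truth intergenic regions), and the echoed
#'   `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::local_seed(spec$seed)
  contigs <- vector("list", spec$n_contigs)
  genes <- vector("list", spec$n_contigs)
  motifs <- vector("list", spec$n_contigs)
  igrs <- vector("list", spec$n_contigs)
  n <- spec$genes_per_contig

  for (ci in seq_len(spec$n_contigs)) {
    cname <- sprintf("contig_%03d", ci)
    roles <- sample(names(spec$role_mix), n, replace = TRUE,
                    prob = spec$role_mix)
    # plant islands: interior genes non-housekeeping with >=1 defense,
    # immediate flanks housekeeping
    for (isl in spec$islands) {
      if (isl$contig != ci) next
      idx <- seq(isl$at_gene, isl$at_gene + isl$n_genes - 1)
      roles[idx] <- sample(c("defense", "other"), length(idx),
                           replace = TRUE, prob = c(0.6, 0.4))
      roles[idx[1]] <- "defense"
      if (isl$at_gene > 1) roles[isl$at_gene - 1] <- "housekeeping"
      if (max(idx) < n) roles[max(idx) + 1] <- "housekeeping"
    }
    glen <- sample(spec$gene_length_range[1]:spec$gene_length_range[2], n,
                   replace = TRUE)
    ilen <- sample(spec$igr_length_range[1]:spec$igr_length_range[2], n + 1,
                   replace = TRUE)

    planted <- purrr::keep(spec$motif_plants, ~ .x$contig == ci)
    for (mp in planted) {
      need <- nchar(mp$seq) + 10L
      if (ilen[mp$igr_index + 1] < need) ilen[mp$igr_index + 1] <- need
    }

    igr_seq <- rand_dna(n + 1, ilen)
    motif_rows <- list()
    for (mp in planted) {
      i <- mp$igr_index + 1L
      ins <- if (identical(mp$strand, "-")) revcomp(mp$seq) else mp$seq
      off <- sample.int(ilen[i] - nchar(ins) + 1L, 1) - 1L
      substr(igr_seq[i], off + 1L, off + nchar(ins)) <- ins
      motif_rows[[length(motif_rows) + 1]] <- tibble(
        contig = cname, igr_index = mp$igr_index, offset_in_igr = off,
        strand = mp$strand %||% "+", seq = mp$seq, width = nchar(mp$seq))
    }

    gene_seq <- rand_dna(n, glen)
    # contig layout: igr0 gene1 igr1 gene2 ... geneN igrN
    starts <- integer(n); ends <- integer(n); pos <- ilen[1]
    for (gi in seq_len(n)) {
      starts[gi] <- pos
      ends[gi] <- pos + glen[gi]
      pos <- ends[gi] + ilen[gi + 1]
    }
    seqs <- character(2 * n + 1)
    seqs[seq(1, 2 * n + 1, by = 2)] <- igr_seq
    seqs[seq(2, 2 * n, by = 2)] <- gene_seq
    contig_seq <- paste(seqs, collapse = "")

    prot <- character(n)
    for (gi in seq_len(n)) {
      cons <- switch(roles[gi],
        defense = spec$defense_consensus,
        housekeeping = spec$housekeeping_consensus,
        NULL)
      prot[gi] <- if (is.null(cons)) {
        rand_protein(1, max(50L, glen[gi] %/% 3L))
      } else {
        mutate_seq(sample(cons, 1), 0.05, AA_ALPHABET)
      }
    }

    genes[[ci]] <- tibble(
      contig = cname,
      gene_id = sprintf("%s_g%03d", cname, seq_len(n)),
      start = starts, end = ends,
      strand = sample(c("+", "-"), n, replace = TRUE),
      role = roles, protein = prot
    )
    contigs[[ci]] <- tibble(contig = cname, seq = contig_seq)

    # IGR truth: regions strictly between genes and at contig termini
    istart <- c(0L, ends)
    iend <- c(starts, nchar(contig_seq))
    igrs[[ci]] <- tibble(contig = cname, igr_index = 0:n,
                         start = istart, end = iend)
    if (length(motif_rows)) {
      mr <- bind_rows(motif_rows)
      mr$start <- istart[mr$igr_index + 1L] + mr$offset_in_igr
      mr$end <- mr$start + mr$width
      motifs[[ci]] <- select(mr, "contig", "igr_index", "start", "end",
                             "strand", "seq")
    }
  }

  genes <- bind_rows(genes)
  out <- list(
    genome = bind_rows(contigs),
    genes = genes,
    islands = islands_from_roles(genes),
    motifs = if (length(purrr::compact(motifs)))
      bind_rows(motifs) else
      tibble(contig = character(), igr_index = integer(), start = integer(),
             end = integer(), strand = character(), seq = character()),
    igrs = bind_rows(igrs),
    spec = spec
  )
  out
}

# Truth islands: maximal runs of non-housekeeping genes containing >=1
# defense gene, bounded by housekeeping genes or contig edges.
islands_from_roles <- function(genes) {
  genes |>
    arrange(.data$contig, .data$start) |>
    split(~contig) |>
    imap(function(g, ct) {
      mutate(island_scan(g$gene_id, g$role, g$start, g$end), contig = ct,
             .before = 1)
    }) |>
    list_rbind() |>
    mutate(island_id = sprintf("isl_%03d", row_number()))
}

island_scan <- function(ids, roles, starts, ends) {
  n <- length(ids)
  out <- list()
  i <- 1
  while (i <= n) {
    if (roles[i] == "housekeeping") { i <- i + 1; next }
    j <- i
    while (j < n && roles[j + 1] != "housekeeping") j <- j + 1
    nd <- sum(roles[i:j] == "defense")
    if (nd >= 1) {
      out[[length(out) + 1]] <- tibble(
        island_id = NA_character_,
        first_gene = ids[i], last_gene = ids[j],
        members = list(ids[i:j]),
        start = starts[i], end = ends[j],
        n_defense = nd, n_genes = j - i + 1,
        left_flank = if (i > 1) ids[i - 1] else NA_character_,
        right_flank = if (j < n) ids[j + 1] else NA_character_,
        edge = i == 1 || j == n
      )
    }
    i <- j + 1
  }
  if (!length(out)) {
    return(tibble(island_id = character(), first_gene = character(),
                  last_gene = character(), members = list(),
                  start = integer(), end = integer(), n_defense = integer(),
                  n_genes = integer(), left_flank = character(),
                  right_flank = character(), edge = logical()))
  }
  res <- bind_rows(out)
  res$island_id <- sprintf("isl_%02d", seq_len(nrow(res)))
  res
}

#' Generate synthetic protein families with known membership
#'
#' Each family is a random consensus protein; members are independent
#' point-substituted copies at the spec's divergence. Every member carries
#' a 7-rank lineage so taxonomy consensus and per-species representative
#' selection can be exercised against truth.
#'
#' @param spec A [family_spec()].
#' @return List with `proteins` (tibble `protein_id`, `seq`, `family`,
#'   `species`, `lineage`), `consensus` (tibble `family`, `seq`) and the
#'   echoed `spec`.
#' @export
generate_families <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  withr::local_seed(spec$seed)
  cons <- rand_protein(spec$n_families, spec$consensus_length)
  rows <- list()
  for (f in seq_len(spec$n_families)) {
    for (m in seq_len(spec$members_per_family)) {
      id <- sprintf("fam%02d_m%02d", f, m)
      lineage <- spec$species_labels[[id]] %||% sprintf(
        "d__Bacteria;p__Phylum%02d;c__Class%02d;o__Order%02d;f__Family%02d;g__Genus%02d;s__Species%02d",
        (f - 1) %/% 4 + 1, (f - 1) %/% 2 + 1, f, f, f, f)
      rows[[length(rows) + 1]] <- tibble(
        protein_id = id,
        seq = mutate_seq(cons[f], spec$divergence, AA_ALPHABET),
        family = sprintf("fam%02d", f),
        species = sub(".*;s__", "", lineage),
        lineage = lineage
      )
    }
  }
  list(proteins = bind_rows(rows),
       consensus = tibble(family = sprintf("fam%02d", seq_len(spec$n_families)),
                          seq = cons),
       spec = spec)
}
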