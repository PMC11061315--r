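#' Position-frequency profiles for protein role annotation
#'
#' A profile database is a list of position-frequency models over amino
#' acids, the desk-scale stand-in for HMM / PSSM domain libraries. A
#' profile is built from equal-length (ungapped-aligned) member sequences
#' with a Laplace pseudocount.
#'
#' @param id Profile identifier.
#' @param seqs Character vector of equal-length protein sequences.
#' @param pseudocount Laplace pseudocount added per residue per column.
#' @return A `seq_profile` list: `id`, `pfm` (20 x L frequency matrix),
#'   `log_odds` (base-2, uniform background 1/20), `consensus`.
#' @export
profile_from_seqs <- function(id, seqs, pseudocount = 1) {
  if (length(unique(nchar(seqs))) != 1) {
    abort("profile member sequences must have equal length")
  }
  L <- nchar(seqs[1])
  mat <- do.call(rbind, strsplit(seqs, ""))
  pfm <- vapply(seq_len(L), function(j) {
    cnt <- table(factor(mat[, j], levels = AA_ALPHABET)) + pseudocount
    as.numeric(cnt / sum(cnt))
  }, numeric(20))
  rownames(pfm) <- AA_ALPHABET
  new_tnpb_result(list(
    id = id, pfm = pfm, log_odds = log2(pfm / (1 / 20)),
    consensus = paste(AA_ALPHABET[apply(pfm, 2, which.max)], collapse = "")
  ), "seq_profile")
}

# Best ungapped placement score of each sequence against a log-odds
# matrix; the shorter of sequence and profile slides inside the longer.
# idx_mat: n x len integer matrix of residue indices (rows of lo).
profile_best_scores <- function(idx_mat, lo) {
  n <- nrow(idx_mat); len <- ncol(idx_mat); L <- ncol(lo)
  if (len >= L) {
    noff <- len - L + 1L
    S <- matrix(0, n, noff)
    for (k in seq_len(L)) {
      S <- S + matrix(lo[, k][idx_mat[, k:(k + noff - 1), drop = FALSE]],
                      n, noff)
    }
  } else {
    noff <- L - len + 1L
    S <- matrix(0, n, noff)
    for (j in seq_len(len)) {
      S <- S + matrix(lo[idx_mat[, j], j:(j + noff - 1), drop = FALSE],
                      n, noff)
    }
  }
  apply(S, 1, max)
}

score_against_profile <- function(seqs, profile) {
  lens <- nchar(seqs)
  out <- numeric(length(seqs))
  for (l in unique(lens)) {
    sel <- lens == l
    idx <- do.call(rbind, lapply(strsplit(seqs[sel], ""), match,
                                 table = AA_ALPHABET))
    out[sel] <- profile_best_scores(idx, profile$log_odds)
  }
  out
}

#' Annotate gene roles against defense and housekeeping profile databases
#'
#' Each protein is scored against every profile by its best ungapped
#' placement (summed base-2 log-odds). Significance is an e-value-like
#' upper-tail probability calibrated from random-sequence nulls per length
#' bin with a Gumbel tail fit, mirroring how domain-search e-values behave.
#' A gene is `defense` if its best defense-profile significance passes the
#' strict threshold, else `housekeeping` if that database's looser
#' threshold passes, else `other`; defense takes precedence when both pass
#' (its threshold is the stricter of the two).
#'
#' @param genes Tibble with `gene_id` and `protein` columns.
#' @param defense_db,housekeeping_db Lists of [profile_from_seqs()]
#'   profiles.
#' @param defense_threshold,housekeeping_threshold Significance cutoffs
#'   (defaults 1e-4 and 1e-2).
#' @param n_null Null sequences per length bin for calibration.
#' @param bin_width Length-bin width (aa).
#' @param seed Seed for the calibration null.
#' @return Tibble `gene_id`, `role`, `best_profile`, `score`,
#'   `significance`.
#' @export
annotate_roles <- function(genes, defense_db, housekeeping_db,
                           defense_threshold = 1e-4,
                           housekeeping_threshold = 1e-2,
                           n_null = 1000, bin_width = 50, seed = 1L) {
  if (!length(defense_db) || !length(housekeeping_db)) {
    abort("profile databases must be non-empty")
  }
  withr::local_seed(seed)
  prots <- genes$protein
  lens <- nchar(prots)
  bins <- pmax(1L, as.integer(ceiling(lens / bin_width)))
  null_cache <- new.env(parent = emptyenv())

  best_hit <- function(db, prefix) {
    sig <- matrix(NA_real_, length(prots), length(db))
    sco <- matrix(NA_real_, length(prots), length(db))
    for (pi in seq_along(db)) {
      prof <- db[[pi]]
      sco[, pi] <- ifelse(lens == 0, -Inf, NA)
      ok <- lens > 0
      if (any(ok)) sco[ok, pi] <- score_against_profile(prots[ok], prof)
      for (b in unique(bins[ok])) {
        key <- paste(prefix, pi, b)
        if (is.null(null_cache[[key]])) {
          null_len <- as.integer(b * bin_width - bin_width / 2)
          null_seqs <- rand_protein(n_null, null_len)
          null_cache[[key]] <- score_against_profile(null_seqs, prof)
        }
        sel <- ok & bins == b
        sig[sel, pi] <- gumbel_tail_p(sco[sel, pi], null_cache[[key]])
      }
    }
    j <- apply(sig, 1, function(r) if (all(is.na(r))) NA_integer_ else
      which.min(r))
    tibble(profile = map_chr(db, "id")[j],
           score = sco[cbind(seq_along(j), j)],
           significance = sig[cbind(seq_along(j), j)])
  }

  def <- best_hit(defense_db, "D")
  hk <- best_hit(housekeeping_db, "H")
  role <- rep("other", length(prots))
  role[!is.na(hk$significance) &
         hk$significance <= housekeeping_threshold] <- "housekeeping"
  role[!is.na(def$significance) &
         def$significance <= defense_threshold] <- "defense"
  if (any(lens == 0)) {
    warn("empty protein sequence(s): assigned role 'other'")
    role[lens == 0] <- "other"
  }
  take_def <- role == "defense"
  tibble(
    gene_id = genes$gene_id,
    role = role,
    best_profile = ifelse(take_def, def$profile, hk$profile),
    score = ifelse(take_def, def$score, hk$score),
    significance = ifelse(take_def, def$significance, hk$significance)
  )
}

#' Call defense islands from ordered role annotations
#'
#' A defense island is a maximal run of non-housekeeping genes containing
#' at least one defense gene, bounded on each side by a housekeeping gene
#' or a contig edge (edge-bounded islands are flagged).
#'
#' @param genes Tibble with `contig`, `gene_id`, `start`, `end`, `role`.
#' @return Tibble of islands: `contig`, `island_id`, `first_gene`,
#'   `last_gene`, `members` (list-column), `start`, `end`, `n_defense`,
#'   `n_genes`, `left_flank`, `right_flank`, `edge`.
#' @export
call_islands <- function(genes) {
  stopifnot(all(c("contig", "gene_id", "start", "end", "role") %in%
                  names(genes)))
  islands_from_roles(genes)
}

#' Extract intergenic regions
#'
#' Overlapping gene spans are merged first; IGRs are the regions strictly
#' between consecutive merged spans plus the contig termini, discarding
#' those shorter than `min_len` (default 15 nt). If an island table is
#' supplied, IGRs falling inside an island span are flagged.
#'
#' @param genes Gene tibble (`contig`, `gene_id`, `start`, `end`).
#' @param genome Tibble `contig`, `seq` (for contig lengths and IGR
#'   sequence extraction).
#' @param min_len Minimum IGR length kept.
#' @param islands Optional island tibble from [call_islands()].
#' @return Tibble `igr_id`, `contig`, `start`, `end`, `left_gene`,
#'   `right_gene`, `inside_island`, `seq`.
#' @export
extract_igrs <- function(genes, genome, min_len = 15, islands = NULL) {
  out <- list()
  for (ci in genome$contig) {
    clen <- nchar(genome$seq[genome$contig == ci])
    g <- filter(genes, .data$contig == ci) |> arrange(.data$start)
    merged <- if (nrow(g)) {
      IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    } else IRanges::IRanges()
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, clen), merged)
    if (!length(gaps)) next
    start <- IRanges::start(gaps) - 1L
    end <- IRanges::end(gaps)
    keep <- (end - start) >= min_len
    start <- start[keep]; end <- end[keep]
    if (!length(start)) next
    left <- map_chr(start, function(s) {
      cand <- g$gene_id[g$end <= s]
      if (length(cand)) cand[which.max(g$end[g$end <= s])] else NA_character_
    })
    right <- map_chr(end, function(e) {
      cand <- g$gene_id[g$start >= e]
      if (length(cand)) cand[which.min(g$start[g$start >= e])] else
        NA_character_
    })
    inside <- rep(FALSE, length(start))
    if (!is.null(islands)) {
      isl <- filter(islands, .data$contig == ci)
      for (k in seq_len(nrow(isl))) {
        inside <- inside | (start >= isl$start[k] & end <= isl$end[k])
      }
    }
    out[[ci]] <- tibble(
      contig = ci, start = start, end = end,
      left_gene = left, right_gene = right, inside_island = inside,
      seq = substr(rep(genome$seq[genome$contig == ci], length(start)),
                   start + 1L, end)
    )
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(contig = character(), start = integer(), end = integer(),
           left_gene = character(), right_gene = character(),
           inside_island = logical(), seq = character())
  res$igr_id <- if (nrow(res)) sprintf("igr_%04d", seq_len(nrow(res))) else
    character()
  select(res, "igr_id", "contig", "start", "end", "left_gene",
         "right_gene", "inside_island", "seq")
}

#' Gene neighborhood around an RNA hit
#'
#' Returns the up-to-k nearest genes on each side of each hit, in genomic
#' order, truncated at contig edges. Genes overlapping the hit itself are
#' excluded.
#'
#' @param hits Tibble with `hit_id`, `contig`, `start`, `end`.
#' @param genes Gene tibble (`contig`, `gene_id`, `start`, `end`).
#' @param k Maximum genes per side (default 5).
#' @return Tibble `hit_id`, `gene_id`, `side` (`upstream`/`downstream`),
#'   `rank` (1 = nearest), `distance` (nt).
#' @export
neighborhood <- function(hits, genes, k = 5) {
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    g <- filter(genes, .data$contig == h$contig)
    up <- filter(g, .data$end <= h$start) |> arrange(desc(.data$end)) |>
      slice_head(n = k)
    dn <- filter(g, .data$start >= h$end) |> arrange(.data$start) |>
      slice_head(n = k)
    if (nrow(up)) rows[[length(rows) + 1]] <- tibble(
      hit_id = h$hit_id, gene_id = up$gene_id, side = "upstream",
      rank = seq_len(nrow(up)), distance = h$start - up$end)
    if (nrow(dn)) rows[[length(rows) + 1]] <- tibble(
      hit_id = h$hit_id, gene_id = dn$gene_id, side = "downstream",
      rank = seq_len(nrow(dn)), distance = dn$start - h$end)
  }
  if (!length(rows)) {
    return(tibble(hit_id = character(), gene_id = character(),
                  side = character(), rank = integer(),
                  distance = integer()))
  }
  bind_rows(rows)
}
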