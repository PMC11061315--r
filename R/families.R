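blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

pair_stats_set <- function(queries, subject, gap_open = 10, gap_extend = 1) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject),
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_extend, type = "local")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")
  stats <- map2(ap, as_, function(p, s) {
    both <- p != "-" & s != "-"
    c(identical = sum(p[both] == s[both]), aligned = sum(both))
  })
  aligned <- map_dbl(stats, "aligned")
  identical <- map_dbl(stats, "identical")
  tibble(
    identity = ifelse(aligned > 0, identical / aligned, 0),
    coverage = aligned / pmin(nchar(queries), nchar(subject)),
    score = Biostrings::score(pa)
  )
}

#' Pairwise local protein alignment with identity and coverage
#'
#' Smith-Waterman local alignment with affine gaps (BLOSUM62). Identity is
#' the fraction of identical residues among columns where both sequences
#' are ungapped; coverage is the number of such columns divided by the
#' shorter sequence length; `similarity` is their product, the score used
#' for cluster similarity summaries.
#'
#' @param a,b Protein sequences (character scalars).
#' @param gap_open,gap_extend Affine gap penalties.
#' @return One-row tibble `identity`, `coverage`, `similarity`, `score`.
#' @export
align_pair <- function(a, b, gap_open = 10, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  st <- pair_stats_set(a, b, gap_open, gap_extend)
  mutate(st, similarity = .data$identity * .data$coverage,
         .before = "score")
}

#' Greedy identity clustering of proteins
#'
#' Proteins are processed in descending length order; each joins the first
#' existing cluster whose representative it matches at or above both the
#' identity and coverage thresholds, otherwise it founds a new cluster
#' with itself as representative.
#'
#' @param proteins Tibble with `protein_id`, `seq`.
#' @param min_identity,min_coverage Thresholds (defaults 0.3 and 0.6).
#' @return Tibble `cluster_id`, `representative`, `protein_id`.
#' @export
greedy_cluster <- function(proteins, min_identity = 0.3,
                           min_coverage = 0.6) {
  ord <- order(-nchar(proteins$seq), proteins$protein_id)
  p <- proteins[ord, ]
  rep_seq <- character(); rep_id <- character()
  assign <- integer(nrow(p))
  for (i in seq_len(nrow(p))) {
    joined <- 0L
    if (length(rep_seq)) {
      st <- pair_stats_set(rep_seq, p$seq[i])
      hit <- which(st$identity >= min_identity &
                     st$coverage >= min_coverage)
      if (length(hit)) joined <- hit[1]
    }
    if (joined == 0L) {
      rep_seq <- c(rep_seq, p$seq[i])
      rep_id <- c(rep_id, p$protein_id[i])
      joined <- length(rep_seq)
    }
    assign[i] <- joined
  }
  tibble(cluster_id = sprintf("icl_%03d", assign),
         representative = rep_id[assign],
         protein_id = p$protein_id) |>
    arrange(.data$cluster_id, .data$protein_id)
}

# Star multiple alignment anchored on the longest member: each member is
# globally aligned to the anchor and its residues mapped onto anchor
# columns (insertions relative to the anchor are dropped).
star_alignment <- function(seqs) {
  anchor <- seqs[order(-nchar(seqs))[1]]
  L <- nchar(anchor)
  rows <- vapply(seqs, function(s) {
    if (s == anchor) return(anchor)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s), Biostrings::AAString(anchor),
      substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 1,
      type = "global")
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    a <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    paste(p[a != "-"], collapse = "")
  }, character(1))
  rows
}

#' Build a cluster sequence profile by star alignment
#'
#' Members are star-aligned on the longest member and column amino-acid
#' frequencies computed with Laplace pseudocount 1, a deterministic
#' profile-lite stand-in for an HMM built from a full MSA.
#'
#' @param members Tibble with `protein_id`, `seq` (one cluster's members).
#' @param id Profile / cluster id.
#' @return A `seq_profile` (see [profile_from_seqs()]).
#' @export
build_cluster_profile <- function(members, id = "cluster") {
  stopifnot(nrow(members) >= 1)
  aligned <- star_alignment(members$seq)
  prof <- profile_from_seqs(id, aligned, pseudocount = 1)
  prof$members <- members$protein_id
  prof
}

#' Profile-similarity graph over proteins
#'
#' The directed affinity of protein i for cluster c is its best-placement
#' profile score against c's profile divided by its score against its own
#' cluster's profile; the undirected edge weight between i and j averages
#' the two cross-affinities and is clipped to [0, 1]. Edges whose
#' cross-scores fail the calibrated significance cutoff (random-sequence
#' null with Gumbel tail, the package's e-value analogue) are dropped.
#' Within-cluster edges are kept at weight from the shared profile.
#'
#' @param proteins Tibble `protein_id`, `seq`.
#' @param clusters Tibble `cluster_id`, `protein_id` from
#'   [greedy_cluster()].
#' @param profiles Named list of cluster profiles from
#'   [build_cluster_profile()]; built on the fly when `NULL`.
#' @param significance Cutoff on the calibrated tail probability
#'   (default 1e-5).
#' @param n_null Null sequences per profile for calibration.
#' @param seed Seed for the calibration null.
#' @return List with `edges` (tibble `from`, `to`, `weight`) and `nodes`.
#' @export
similarity_graph <- function(proteins, clusters, profiles = NULL,
                             significance = 1e-5, n_null = 500,
                             seed = 1L) {
  withr::local_seed(seed)
  cl_ids <- sort(unique(clusters$cluster_id))
  if (is.null(profiles)) {
    profiles <- lapply(cl_ids, function(cid) {
      build_cluster_profile(
        left_join(filter(clusters, .data$cluster_id == cid), proteins,
                  by = "protein_id"), id = cid)
    })
    names(profiles) <- cl_ids
  }
  own <- setNames(clusters$cluster_id, clusters$protein_id)
  n <- nrow(proteins)

  # per-protein score against every cluster profile + calibrated p-value
  sco <- matrix(NA_real_, n, length(cl_ids),
                dimnames = list(proteins$protein_id, cl_ids))
  sig <- sco
  med_len <- as.integer(stats::median(nchar(proteins$seq)))
  for (ci in seq_along(cl_ids)) {
    prof <- profiles[[cl_ids[ci]]]
    sco[, ci] <- score_against_profile(proteins$seq, prof)
    null_scores <- score_against_profile(rand_protein(n_null, med_len), prof)
    sig[, ci] <- gumbel_tail_p(sco[, ci], null_scores)
  }
  self <- sco[cbind(seq_len(n), match(own[proteins$protein_id], cl_ids))]

  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ci <- match(own[proteins$protein_id[j]], cl_ids)
      cj <- match(own[proteins$protein_id[i]], cl_ids)
      same <- cl_ids[ci] == cl_ids[cj]
      if (!same && sig[i, ci] > significance && sig[j, cj] > significance) {
        next
      }
      w <- mean(c(sco[i, ci] / self[i], sco[j, cj] / self[j]))
      w <- min(max(w, 0), 1)
      if (w > 0) edges[[length(edges) + 1]] <- tibble(
        from = proteins$protein_id[i], to = proteins$protein_id[j],
        weight = w)
    }
  }
  list(edges = if (length(edges)) bind_rows(edges) else
         tibble(from = character(), to = character(), weight = numeric()),
       nodes = proteins$protein_id)
}

#' Markov clustering (MCL)
#'
#' Column-stochastic flow simulation: expansion (matrix self-product)
#' alternating with inflation (elementwise power, column renormalisation)
#' and pruning of small entries, iterated to a fixed point. Clusters are
#' the weakly connected components of the attractor support; attractor
#' rows sharing support are merged.
#'
#' @param graph A list with `edges`/`nodes` (from [similarity_graph()]) or
#'   a symmetric non-negative weight matrix with dimnames.
#' @param inflation Inflation exponent (default 2.0).
#' @param prune Entries below this are zeroed each iteration.
#' @param tol Convergence tolerance on max absolute change.
#' @param max_iter Iteration cap; non-convergence returns a warning flag.
#' @return List with `clusters` (tibble `cluster_id`, `representative`,
#'   `protein_id`), `converged`, `iterations`.
#' @export
mcl <- function(graph, inflation = 2.0, prune = 1e-5, tol = 1e-6,
                max_iter = 100) {
  if (is.matrix(graph)) {
    A <- graph
    nodes <- rownames(A) %||% as.character(seq_len(nrow(A)))
  } else {
    nodes <- graph$nodes
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    e <- graph$edges
    for (k in seq_len(nrow(e))) {
      A[e$from[k], e$to[k]] <- e$weight[k]
      A[e$to[k], e$from[k]] <- e$weight[k]
    }
  }
  if (max(abs(A - t(A))) > 1e-12) abort("graph must be symmetric")
  n <- nrow(A)
  # self-loops: max incident weight (1 for isolated nodes)
  for (i in seq_len(n)) {
    if (A[i, i] == 0) {
      inc <- max(A[i, ])
      A[i, i] <- if (inc > 0) inc else 1
    }
  }
  colnorm <- function(M) {
    cs <- colSums(M)
    cs[cs == 0] <- 1
    sweep(M, 2, cs, "/")
  }
  M <- colnorm(A)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    M2 <- colnorm(M2)
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      converged <- TRUE
      break
    }
    M <- M2
  }
  if (!converged) warn("MCL did not converge within max_iter")
  clusters <- mcl_extract_clusters(M, nodes)
  list(clusters = clusters, converged = converged, iterations = it)
}

mcl_extract_clusters <- function(M, nodes, eps = 1e-6) {
  n <- length(nodes)
  attractors <- which(diag(M) > eps)
  if (!length(attractors)) attractors <- seq_len(n)
  support <- lapply(attractors, function(a) which(M[a, ] > eps))
  # merge attractors with overlapping support (weak components)
  comp <- seq_along(attractors)
  repeat {
    changed <- FALSE
    for (a in seq_along(attractors)) {
      for (b in seq_along(attractors)) {
        if (comp[a] != comp[b] &&
            length(intersect(support[[a]], support[[b]]))) {
          comp[comp == comp[b]] <- comp[a]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  assign <- rep(NA_integer_, n)
  for (a in seq_along(attractors)) assign[support[[a]]] <- comp[a]
  for (i in which(is.na(assign))) {
    best <- which.max(M[, i])
    hit <- which(vapply(seq_along(attractors), function(a)
      best %in% support[[a]], logical(1)))
    assign[i] <- if (length(hit)) comp[hit[1]] else -i
  }
  ids <- match(assign, sort(unique(assign)))
  out <- tibble(protein_id = nodes, cl = ids) |>
    group_by(.data$cl) |>
    mutate(representative = .data$protein_id[1]) |>
    ungroup()
  tibble(cluster_id = sprintf("fam_%03d", out$cl),
         representative = out$representative,
         protein_id = out$protein_id) |>
    arrange(.data$cluster_id, .data$protein_id)
}

#' Two-step protein family clustering
#'
#' The full re-clustering procedure: greedy identity clustering, a
#' star-alignment profile per initial cluster, a profile-similarity graph,
#' and Markov clustering of that graph into final families.
#'
#' @param proteins Tibble `protein_id`, `seq`.
#' @param min_identity,min_coverage Greedy-step thresholds.
#' @param inflation MCL inflation.
#' @param significance Graph edge significance cutoff.
#' @param seed Seed for graph calibration.
#' @return List `initial` (greedy clusters), `graph`, `final` (MCL result),
#'   `clusters` (final tibble `cluster_id`, `representative`,
#'   `protein_id`).
#' @export
two_step_cluster <- function(proteins, min_identity = 0.3,
                             min_coverage = 0.6, inflation = 2.0,
                             significance = 1e-5, seed = 1L) {
  initial <- greedy_cluster(proteins, min_identity, min_coverage)
  graph <- similarity_graph(proteins, initial, significance = significance,
                            seed = seed)
  final <- mcl(graph, inflation = inflation)
  list(initial = initial, graph = graph, final = final,
       clusters = final$clusters)
}

#' Remove redundant proteins
#'
#' Greedy longest-first representative selection: a protein is dropped if
#' it aligns to an already-kept representative at or above the identity
#' threshold (default 0.9).
#'
#' @param proteins Tibble `protein_id`, `seq`.
#' @param min_identity Redundancy threshold.
#' @return Tibble of representatives (`protein_id`, `seq`) with a
#'   `removed` attribute mapping dropped ids to their representative.
#' @export
dedupe <- function(proteins, min_identity = 0.9) {
  ord <- order(-nchar(proteins$seq), proteins$protein_id)
  p <- proteins[ord, ]
  keep <- integer(); removed <- list()
  for (i in seq_len(nrow(p))) {
    hit <- 0L
    if (length(keep)) {
      st <- pair_stats_set(p$seq[keep], p$seq[i])
      w <- which(st$identity >= min_identity)
      if (length(w)) hit <- keep[w[1]]
    }
    if (hit == 0L) keep <- c(keep, i) else
      removed[[p$protein_id[i]]] <- p$protein_id[hit]
  }
  out <- p[keep, ]
  attr(out, "removed") <- removed
  out
}

RANKS <- c("superkingdom", "phylum", "class", "order", "family", "genus",
           "species")

split_lineage <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)
  map(parts, function(p) {
    p <- sub("^[a-z]__", "", trimws(p))
    length(p) <- 7
    p
  })
}

#' Contig taxonomy by protein consensus cross-checked with a nucleotide hit
#'
#' Protein best-hit lineages are filtered (identity > 0.4, coverage >
#' 0.7); the protein consensus is the most specific rank with > 70%
#' agreement among annotated proteins. The assignment is adopted only when
#' the nucleotide-method lineage carries the same label at that rank,
#' otherwise the contig is `undetermined`.
#'
#' @param protein_hits Tibble `contig`, `protein_id`, `lineage`,
#'   `identity`, `coverage`; `lineage` is a 7-rank semicolon string
#'   (missing lineages are excluded from the denominator).
#' @param contig_hits Tibble `contig`, `lineage` from the nucleotide
#'   method.
#' @param min_identity,min_coverage,min_agreement Filters and the
#'   agreement threshold.
#' @return Tibble `contig`, `status`, `assigned_rank`, `label`,
#'   `agreement`, `n_proteins`.
#' @export
assign_taxonomy <- function(protein_hits, contig_hits, min_identity = 0.4,
                            min_coverage = 0.7, min_agreement = 0.7) {
  ph <- filter(protein_hits, !is.na(.data$lineage),
               .data$identity > min_identity,
               .data$coverage > min_coverage)
  rows <- list()
  for (ct in unique(c(protein_hits$contig, contig_hits$contig))) {
    sub <- filter(ph, .data$contig == ct)
    if (!nrow(sub)) {
      rows[[ct]] <- tibble(contig = ct, status = "undetermined",
                           assigned_rank = NA_character_,
                           label = NA_character_, agreement = NA_real_,
                           n_proteins = 0L)
      next
    }
    lin <- split_lineage(sub$lineage)
    cons_rank <- NA_integer_; cons_label <- NA_character_; cons_agr <- NA_real_
    for (r in 7:1) {
      labs <- map_chr(lin, r)
      labs <- labs[!is.na(labs) & nzchar(labs)]
      if (!length(labs)) next
      tab <- sort(table(labs), decreasing = TRUE)
      agr <- tab[1] / nrow(sub)
      if (agr > min_agreement) {
        cons_rank <- r; cons_label <- names(tab)[1]
        cons_agr <- as.numeric(agr)
        break
      }
    }
    nuc <- filter(contig_hits, .data$contig == ct)
    nuc_label <- if (nrow(nuc)) split_lineage(nuc$lineage[1])[[1]][cons_rank]
      else NA_character_
    ok <- !is.na(cons_rank) && !is.na(nuc_label) &&
      identical(nuc_label, cons_label)
    rows[[ct]] <- tibble(
      contig = ct,
      status = if (ok) "assigned" else "undetermined",
      assigned_rank = if (ok) RANKS[cons_rank] else NA_character_,
      label = if (ok) cons_label else NA_character_,
      agreement = cons_agr, n_proteins = nrow(sub))
  }
  bind_rows(rows)
}

#' RNA motif - protein family co-occurrence
#'
#' For each (motif, family) pair, the fraction of RNA hits whose
#' neighborhood window contains at least one family member, mirroring the
#' gene-neighborhood co-occurrence statistic used to pair a non-coding RNA
#' with its protein partner.
#'
#' @param hits Motif hit tibble with `hit_id` and optionally `motif`
#'   (defaults to a single motif label).
#' @param windows Neighborhood tibble from [neighborhood()] (`hit_id`,
#'   `gene_id`).
#' @param clusters Final family tibble (`cluster_id`, `protein_id`), with
#'   protein ids matching the window gene ids.
#' @return Tibble `motif`, `cluster_id`, `n_adjacent`, `n_hits`,
#'   `fraction`, sorted by descending fraction.
#' @export
cooccurrence <- function(hits, windows, clusters) {
  hits <- mutate(hits, motif = if ("motif" %in% names(hits)) .data$motif
                 else "motif")
  memb <- left_join(windows, clusters,
                    by = c(gene_id = "protein_id"),
                    relationship = "many-to-many")
  totals <- hits |> group_by(.data$motif) |>
    summarise(n_hits = dplyr::n_distinct(.data$hit_id), .groups = "drop")
  counts <- hits |>
    select("hit_id", "motif") |>
    left_join(memb, by = "hit_id", relationship = "many-to-many") |>
    filter(!is.na(.data$cluster_id)) |>
    distinct(.data$motif, .data$cluster_id, .data$hit_id) |>
    group_by(.data$motif, .data$cluster_id) |>
    summarise(n_adjacent = n(), .groups = "drop")
  counts |>
    left_join(totals, by = "motif") |>
    mutate(fraction = .data$n_adjacent / .data$n_hits) |>
    arrange(desc(.data$fraction), .data$cluster_id)
}

#' Taxonomy-capped representative selection
#'
#' Keeps at most `max_per_species` proteins per species within each final
#' cluster, longest first with deterministic id tie-break.
#'
#' @param clusters Tibble `cluster_id`, `protein_id`.
#' @param taxonomy Tibble `protein_id`, `species`.
#' @param proteins Tibble `protein_id`, `seq` (for lengths).
#' @param max_per_species Cap per species per cluster (default 6).
#' @return Tibble `cluster_id`, `species`, `protein_id` of kept
#'   representatives.
#' @export
select_representatives <- function(clusters, taxonomy, proteins,
                                   max_per_species = 6) {
  clusters |>
    left_join(taxonomy, by = "protein_id") |>
    left_join(proteins, by = "protein_id") |>
    mutate(len = nchar(.data$seq)) |>
    group_by(.data$cluster_id, .data$species) |>
    arrange(desc(.data$len), .data$protein_id, .by_group = TRUE) |>
    slice_head(n = max_per_species) |>
    ungroup() |>
    select("cluster_id", "species", "protein_id")
}
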