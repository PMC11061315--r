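GAP_CHARS <- c("-", ".", "_", "~")
BRACKETS <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))

parse_structure_pairs <- function(ss) {
  chars <- strsplit(ss, "")[[1]]
  pairs <- list()
  for (br in BRACKETS) {
    stack <- integer()
    for (i in seq_along(chars)) {
      if (chars[i] == br[1]) {
        stack <- c(stack, i)
      } else if (chars[i] == br[2]) {
        if (!length(stack)) abort("unbalanced consensus structure string")
        pairs[[length(pairs) + 1]] <- c(stack[length(stack)], i)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack)) abort("unbalanced consensus structure string")
  }
  pairs
}

#' Build a structure-constrained RNA motif model
#'
#' A covariance-model-lite: per-match-column nucleotide log-odds (base 2,
#' uniform background 0.25) plus a list of base-paired column pairs taken
#' from the consensus structure. Match columns are those with gap fraction
#' below `gap_fraction_max`; pairs are retained only when both partners are
#' match columns. The scanner has no insert/delete states, so hits are
#' fixed-length ungapped windows.
#'
#' @param alignment Named character vector of equal-length aligned RNA/DNA
#'   rows (T is read as U), or the `alignment` element of
#'   [read_stockholm()].
#' @param structure Consensus structure string, same length as the
#'   alignment, using balanced `()[]{}<>` brackets; anything else is
#'   unpaired.
#' @param gap_fraction_max Columns with gap fraction below this are match
#'   columns.
#' @param pseudocount Pseudocount per base per column.
#' @param pair_bonus,pair_penalty Score (bits) added for a compatible
#'   (Watson-Crick or G-U) pair, subtracted otherwise.
#' @param name Model name.
#' @return A `motif_model`: `L`, `log_odds` (4 x L, rows A/C/G/U),
#'   `pairs` (list of match-column index pairs), `consensus`,
#'   `pair_bonus`, `pair_penalty`, `name`.
#' @export
build_motif_model <- function(alignment, structure = NULL,
                              gap_fraction_max = 0.5, pseudocount = 0.5,
                              pair_bonus = 1, pair_penalty = 1,
                              name = "motif") {
  if (length(unique(nchar(alignment))) != 1) {
    abort("alignment rows must have equal length")
  }
  W <- nchar(alignment[1])
  if (!is.null(structure) && nchar(structure) != W) {
    abort("structure string length must match the alignment")
  }
  mat <- toupper(do.call(rbind, strsplit(chartr("T", "U", alignment), "")))
  is_gap <- matrix(mat %in% GAP_CHARS, nrow(mat), W)
  gap_frac <- colMeans(is_gap)
  match_cols <- which(gap_frac < gap_fraction_max)
  L <- length(match_cols)
  if (L < 10) abort("model must have at least 10 match columns")

  lo <- vapply(match_cols, function(j) {
    obs <- mat[!is_gap[, j], j]
    cnt <- table(factor(obs, levels = RNA_BASES)) + pseudocount
    f <- as.numeric(cnt) / sum(cnt)
    log2(f / 0.25)
  }, numeric(4))
  rownames(lo) <- RNA_BASES

  pairs <- list()
  if (!is.null(structure)) {
    col_map <- match(seq_len(W), match_cols)
    for (p in parse_structure_pairs(structure)) {
      i <- col_map[p[1]]; j <- col_map[p[2]]
      if (!is.na(i) && !is.na(j)) pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  new_tnpb_result(list(
    L = L, log_odds = lo, pairs = pairs,
    consensus = paste(RNA_BASES[apply(lo, 2, which.max)], collapse = ""),
    pair_bonus = pair_bonus, pair_penalty = pair_penalty, name = name
  ), "motif_model")
}

# Score all length-L windows of one sequence (forward orientation).
score_windows <- function(seq, model) {
  L <- model$L
  idx <- match(strsplit(chartr("T", "U", toupper(seq)), "")[[1]], RNA_BASES)
  n <- length(idx)
  if (n < L) return(numeric(0))
  idx[is.na(idx)] <- 5L  # unknown base: worst-ish column score, no pairing
  lo5 <- rbind(model$log_odds, rep(-2, L))
  noff <- n - L + 1L
  S <- numeric(noff)
  off <- seq_len(noff)
  for (k in seq_len(L)) S <- S + lo5[cbind(idx[off + k - 1L], k)]
  if (length(model$pairs)) {
    comp5 <- rbind(cbind(compatible_pair, FALSE), FALSE)
    for (p in model$pairs) {
      ok <- comp5[cbind(idx[off + p[1] - 1L], idx[off + p[2] - 1L])]
      S <- S + ifelse(ok, model$pair_bonus, -model$pair_penalty)
    }
  }
  S
}

#' Scan intergenic regions for motif hits
#'
#' Every length-L window on both strands is scored as the sum of column
#' log-odds plus the pair term (+bonus for a compatible pair, -penalty
#' otherwise). Windows at or above the threshold are reported after greedy
#' non-overlap resolution (descending score, ties to the leftmost start,
#' then to the + strand).
#'
#' @param igrs Tibble with `igr_id` and `seq` columns; if `contig` and
#'   `start` are present, contig-level hit coordinates are emitted too.
#' @param model A [build_motif_model()].
#' @param threshold Score threshold in bits; defaults to
#'   `null$threshold` when a calibration is supplied.
#' @param null Optional [calibrate_null()] result, used for the default
#'   threshold and for empirical false-positive-rate significance.
#' @return Tibble `hit_id`, `igr_id`, `strand`, `start`, `end` (0-based
#'   half-open within the IGR), `score`, `significance` and, when
#'   available, `contig`, `contig_start`, `contig_end`.
#' @export
scan_motif <- function(igrs, model, threshold = NULL, null = NULL) {
  if (is.null(threshold)) {
    if (is.null(null)) abort("supply a threshold or a calibration")
    threshold <- null$threshold
  }
  L <- model$L
  rows <- list()
  for (i in seq_len(nrow(igrs))) {
    seq <- igrs$seq[i]
    n <- nchar(seq)
    if (n < L) next
    fwd <- score_windows(seq, model)
    rev <- score_windows(revcomp(seq), model)
    cand <- tibble(
      start = c(seq_along(fwd) - 1L, n - seq_along(rev) - L + 1L),
      strand = rep(c("+", "-"), c(length(fwd), length(rev))),
      score = c(fwd, rev)
    ) |> filter(.data$score >= threshold)
    if (!nrow(cand)) next
    cand <- arrange(cand, desc(.data$score), .data$start,
                    .data$strand)
    kept <- integer()
    for (j in seq_len(nrow(cand))) {
      s <- cand$start[j]
      if (!any(abs(cand$start[kept] - s) < L)) kept <- c(kept, j)
    }
    cand <- cand[kept, ]
    cand$igr_id <- igrs$igr_id[i]
    if (all(c("contig", "start") %in% names(igrs))) {
      cand$contig <- igrs$contig[i]
      cand$contig_start <- igrs$start[i] + cand$start
      cand$contig_end <- cand$contig_start + L
    }
    rows[[length(rows) + 1]] <- cand
  }
  if (!length(rows)) {
    return(tibble(hit_id = character(), igr_id = character(),
                  strand = character(), start = integer(), end = integer(),
                  score = numeric(), significance = numeric()))
  }
  hits <- bind_rows(rows)
  hits$end <- hits$start + L
  hits$significance <- if (!is.null(null)) {
    vapply(hits$score, function(s) mean(null$scores >= s), numeric(1))
  } else NA_real_
  hits$hit_id <- sprintf("hit_%04d", seq_len(nrow(hits)))
  cols <- c("hit_id", "igr_id", "strand", "start", "end", "score",
            "significance")
  if ("contig" %in% names(hits)) {
    cols <- c(cols, "contig", "contig_start", "contig_end")
  }
  select(arrange(hits, .data$igr_id, .data$start), dplyr::all_of(cols))
}

#' Calibrate a null score distribution and calling threshold
#'
#' Scores `n` i.i.d. background windows of model length and sets the
#' calling threshold at the empirical `1 - fpr` quantile, an empirical
#' false-positive-rate substitute for covariance-model e-values.
#'
#' @param model A [build_motif_model()].
#' @param n Number of background windows (>= 1000).
#' @param fpr Target per-window false positive rate.
#' @param seed Integer seed.
#' @param background Base probabilities (A, C, G, U).
#' @return List `scores`, `threshold`, `fpr`, `n`.
#' @export
calibrate_null <- function(model, n = 10000, fpr = 1e-3, seed = 1L,
                           background = rep(0.25, 4)) {
  if (n < 1000) abort("n must be >= 1000")
  withr::local_seed(seed)
  windows <- vapply(seq_len(n), function(i) {
    paste(sample(RNA_BASES, model$L, replace = TRUE, prob = background),
          collapse = "")
  }, character(1))
  scores <- vapply(windows, function(w) score_windows(w, model)[1],
                   numeric(1), USE.NAMES = FALSE)
  list(scores = scores,
       threshold = quantile(scores, 1 - fpr, names = FALSE),
       fpr = fpr, n = n)
}
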