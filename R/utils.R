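DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Watson-Crick plus G.U wobble, on RNA alphabet (T folded into U upstream).
compatible_pair <- local({
  m <- matrix(FALSE, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  for (p in list(c("A", "U"), c("U", "A"), c("C", "G"), c("G", "C"),
                 c("G", "U"), c("U", "G"))) {
    m[p[1], p[2]] <- TRUE
  }
  m
})

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' keeps plain character vectors as the working currency of the package.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements, same length as `x`.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rand_dna <- function(n, len) {
  if (length(len) == 1L) len <- rep(len, n)
  vapply(len, function(l) paste(sample(DNA_BASES, l, replace = TRUE),
                                collapse = ""), character(1))
}

rand_protein <- function(n, len) {
  if (length(len) == 1L) len <- rep(len, n)
  vapply(len, function(l) paste(sample(AA_ALPHABET, l, replace = TRUE),
                                collapse = ""), character(1))
}

# Point-substitute characters of `seq` at per-position rate, never
# substituting a character for itself.
mutate_seq <- function(seq, rate, alphabet) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(alphabet, ch), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

seq_to_idx <- function(seq, alphabet) {
  match(strsplit(seq, "")[[1]], alphabet)
}

check_prob_dist <- function(d, what) {
  if (length(d) == 0 || any(d < 0) || abs(sum(d) - 1) > 1e-9) {
    abort(sprintf("%s must be non-negative and sum to 1", what))
  }
  if (is.null(names(d)) || anyNA(suppressWarnings(as.integer(names(d))))) {
    abort(sprintf("%s must be named by integer positions", what))
  }
  if (any(as.integer(names(d)) < 1)) {
    abort(sprintf("%s positions must be >= 1", what))
  }
  invisible(d)
}

# Upper-tail probability under a Gumbel fit (method of moments) to null
# scores; the extrapolated tail stands in for database e-values.
gumbel_tail_p <- function(x, null_scores) {
  s <- sd(null_scores)
  if (!is.finite(s) || s == 0) return(as.numeric(x <= max(null_scores)))
  beta <- s * sqrt(6) / pi
  mu <- mean(null_scores) - 0.5772156649 * beta
  p <- 1 - exp(-exp(-(x - mu) / beta))
  pmax(p, .Machine$double.xmin)
}

new_tnpb_result <- function(x, class) {
  structure(x, class = c(class, "list"))
}
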