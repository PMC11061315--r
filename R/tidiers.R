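#' Tidy and glance methods for result objects
#'
#' Broom-style accessors: `tidy()` returns the per-observation table of a
#' result (per position, per segment, per cell), `glance()` a one-row
#' summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tnpbtools-tidiers
NULL

#' @rdname tnpbtools-tidiers
#' @export
tidy.tam_enrichment <- function(x, ...) {
  tibble(position = rep(1:7, each = 4),
         base = rep(DNA_BASES, 7),
         freq = as.numeric(x$freq),
         enrichment = as.numeric(x$enrichment),
         ic = rep(x$ic, each = 4))
}

#' @rdname tnpbtools-tidiers
#' @export
glance.tam_enrichment <- function(x, ...) {
  tibble(consensus = x$consensus, n = x$n, total_ic = sum(x$ic),
         max_ic = max(x$ic))
}

#' @rdname tnpbtools-tidiers
#' @export
tidy.cut_site_profile <- function(x, ...) x$profile

#' @rdname tnpbtools-tidiers
#' @export
glance.cut_site_profile <- function(x, ...) {
  tibble(ts_mode = x$ts_mode, nts_mode = x$nts_mode,
         ts_mode_fraction = x$ts_mode_fraction,
         nts_mode_fraction = x$nts_mode_fraction,
         overhang = x$overhang, n_discarded = x$n_discarded)
}

#' @rdname tnpbtools-tidiers
#' @export
tidy.rerna_anatomy <- function(x, ...) x$segments

#' @rdname tnpbtools-tidiers
#' @export
glance.rerna_anatomy <- function(x, ...) {
  tibble(transcript_start = x$transcript_start,
         transcript_end = x$transcript_end,
         total_length = x$total_length,
         n_segments = nrow(x$segments),
         truncated = x$truncated, orf_offset = x$orf_offset,
         n_unplaced = x$n_unplaced)
}

#' @rdname tnpbtools-tidiers
#' @export
tidy.indel_report <- function(x, ...) x$histogram

#' @rdname tnpbtools-tidiers
#' @export
glance.indel_report <- function(x, ...) {
  tibble(amplicon_id = x$amplicon_id, total = x$total,
         aligned = x$aligned, edited = x$edited, fraction = x$fraction,
         n_discarded = x$n_discarded)
}

#' @rdname tnpbtools-tidiers
#' @export
tidy.mismatch_heatmap <- function(x, ...) x$table

#' @rdname tnpbtools-tidiers
#' @export
glance.mismatch_heatmap <- function(x, ...) {
  tibble(wt_fraction = x$wt_fraction, guide = x$guide,
         n_zero = sum(x$table$normalized == 0, na.rm = TRUE))
}

#' @export
print.tam_enrichment <- function(x, ...) {
  cat("TAM enrichment over", x$n, "observations\n")
  cat("consensus:", x$consensus, "\n")
  cat("information content (bits):",
      paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.cut_site_profile <- function(x, ...) {
  cat("Cut-site profile: TS mode", x$ts_mode,
      sprintf("(%.2f)", x$ts_mode_fraction),
      "| NTS mode", x$nts_mode, sprintf("(%.2f)", x$nts_mode_fraction),
      "| overhang", sprintf("%+d", x$overhang), "(5' if positive)\n")
  invisible(x)
}

#' @export
print.rerna_anatomy <- function(x, ...) {
  cat("Transcript", x$transcript_start, "-", x$transcript_end,
      "| total", x$total_length, "nt\n")
  print(x$segments)
  invisible(x)
}

#' @export
print.indel_report <- function(x, ...) {
  cat(sprintf("Indel report [%s]: %d/%d edited (%.3f), %d discarded\n",
              x$amplicon_id, x$edited, x$aligned, x$fraction,
              x$n_discarded))
  invisible(x)
}
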