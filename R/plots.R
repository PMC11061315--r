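#' Plot methods for result objects
#'
#' `autoplot()` methods render the standard figure for each result type:
#' a logo-style information-content bar chart for TAM enrichment, per
#' strand cut-position distributions, transcript coverage with segment
#' annotation, a per-position indel histogram, and the guide-mismatch
#' heatmap.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name tnpbtools-plots
NULL

#' @rdname tnpbtools-plots
#' @export
autoplot.tam_enrichment <- function(object, ...) {
  d <- tidy(object) |>
    group_by(.data$position) |>
    mutate(height = .data$freq * .data$ic[1]) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$position),
                                  y = .data$height, fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "TAM position", y = "information (bits)",
                  title = paste("TAM consensus:", object$consensus)) +
    ggplot2::theme_minimal()
}

#' @rdname tnpbtools-plots
#' @export
autoplot.cut_site_profile <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$position, y = .data$fraction)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_wrap(~strand, ncol = 1) +
    ggplot2::labs(x = "cut position (nt from TAM)", y = "fraction of reads") +
    ggplot2::theme_minimal()
}

#' @rdname tnpbtools-plots
#' @export
autoplot.rerna_anatomy <- function(object, ...) {
  ggplot2::ggplot(object$coverage,
                  ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_area(alpha = 0.6) +
    ggplot2::geom_rect(
      data = object$segments, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end, ymin = -Inf,
                   ymax = 0, fill = .data$name)) +
    ggplot2::labs(x = "locus position", y = "coverage") +
    ggplot2::theme_minimal()
}

#' @rdname tnpbtools-plots
#' @export
autoplot.indel_report <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$position, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "reference position", y = "indel-bearing columns",
                  title = sprintf("%s: indel fraction %.3f",
                                  object$amplicon_id, object$fraction)) +
    ggplot2::theme_minimal()
}

#' @rdname tnpbtools-plots
#' @export
autoplot.mismatch_heatmap <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = factor(.data$position), y = .data$base,
                               fill = .data$normalized)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 na.value = "grey95") +
    ggplot2::labs(x = "guide position", y = "substituted base",
                  fill = "norm. efficiency") +
    ggplot2::theme_minimal()
}
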