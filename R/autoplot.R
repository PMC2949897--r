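#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a height track
#'
#' One panel per chromosome; each SNP drawn as a vertical segment of its
#' height, mirroring the raster track bitmaps but as a ggplot for
#' interactive inspection.
#'
#' @param object a `height_track`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.height_track <- function(object, ...) {
  df <- dplyr::mutate(dplyr::group_by(object, .data$chrom),
                      idx = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$idx, y = 0,
                                       yend = .data$height),
                          linewidth = 0.3, colour = "#16366e") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "SNP index", y = "height (0–100)") +
    ggplot2::theme_minimal()
}

#' Manhattan plot as a ggplot
#'
#' Chromosomes concatenated in map order with alternating colours; the y
#' axis is -log10(p) for p-value tables, the raw score for score tables and
#' the flipped rank for rank tables. Always unfiltered.
#'
#' @param table an `assoc_tbl`.
#' @param colors two alternating point colours.
#' @return a ggplot object.
#' @export
plot_manhattan <- function(table, colors = c("#16366e", "#8a9cc9")) {
  kind <- value_kind(table) %||% "score"
  df <- tibble::tibble(
    chrom = table$chrom,
    idx = seq_len(nrow(table)),
    y = manhattan_y(table),
    band = factor(as.integer(table$chrom) %% 2)
  )
  ylab <- switch(kind, pvalue = expression(-log[10](p)),
                 rank = "flipped rank", score = "score")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$y,
                                   colour = .data$band)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = colors) +
    ggplot2::labs(x = "SNP (map order)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @rdname plot_manhattan
#' @param object an `assoc_tbl`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.assoc_tbl <- function(object, ...) plot_manhattan(object)

#' Q-Q plot as a ggplot
#'
#' -log10 expected vs observed p-values with the y = x reference line; the
#' genomic-control corrected series is overlaid when present.
#'
#' @param object a `qq_tbl` from [make_qq_table()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qq_tbl <- function(object, ...) {
  df <- tibble::tibble(expected = -log10(object$expected_p),
                       observed = -log10(object$observed_p),
                       series = "observed")
  if ("gc_p" %in% names(object)) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      expected = -log10(object$expected_p),
      observed = -log10(object$gc_p),
      series = "GC-corrected"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed,
                                   colour = .data$series)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = c(observed = "#16366e",
                                            `GC-corrected` = "#b0413e")) +
    ggplot2::labs(x = expression(-log[10](expected~p)),
                  y = expression(-log[10](observed~p)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.qq_tbl
#' @exportS3Method ggplot2::autoplot
autoplot.gc_result <- function(object, ...) {
  autoplot(make_qq_table(object$p, apply_gc = TRUE))
}
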