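# Thin ggplot2 layer over the exported tables.

#' Heat-map of a median-yield matrix
#'
#' Tile colour is the median yield, tile size the log reaction count,
#' mirroring the size/colour separation of the underlying table.
#'
#' @param matrix_tb output of [median_yield_matrix()].
#' @return a ggplot.
#' @export
plot_yield_matrix <- function(matrix_tb) {
  ggplot2::ggplot(matrix_tb,
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$median_yield,
                               size = log10(.data$n))) +
    ggplot2::geom_point(shape = 22) +
    ggplot2::scale_fill_viridis_c(name = "median yield (%)", limits = c(0, 100)) +
    ggplot2::scale_size_continuous(name = "log10 n") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cheatsheet tile plot
#'
#' @param cheatsheet output of [build_cheatsheet()].
#' @return a ggplot faceted by rank.
#' @export
plot_cheatsheet <- function(cheatsheet) {
  ggplot2::ggplot(cheatsheet,
                  ggplot2::aes(x = .data$nphile_class, y = .data$ephile_class,
                               fill = .data$median_yield)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0(.data$ligand, "\n", .data$base, "\n",
                     round(.data$median_yield), "%")), size = 2.3) +
    ggplot2::scale_fill_viridis_c(name = "median yield (%)", limits = c(0, 100)) +
    ggplot2::facet_wrap(~rank, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "nucleophile class", y = "electrophile class") +
    ggplot2::theme_minimal()
}

#' Yield histogram plot
#'
#' @param hist output of [yield_histogram()].
#' @return a ggplot.
#' @export
plot_yield_histogram <- function(hist) {
  tb <- hist$histogram
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "reported yield (%)", y = "reactions") +
    ggplot2::theme_minimal()
  if ("doc_type" %in% names(tb)) {
    p <- p + ggplot2::facet_wrap(~doc_type, ncol = 1, scales = "free_y")
  }
  p
}

#' Cumulative coverage plot
#'
#' @param coverage output of [cumulative_coverage()] (or a named list of
#'   them, one per reagent kind).
#' @return a ggplot.
#' @export
plot_coverage <- function(coverage) {
  if (!is.data.frame(coverage)) {
    coverage <- dplyr::bind_rows(coverage, .id = "kind")
  } else {
    coverage$kind <- "reagent"
  }
  ggplot2::ggplot(coverage,
                  ggplot2::aes(x = .data$k, y = .data$cum_frac,
                               color = .data$kind)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "top-k reagents", y = "cumulative coverage") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.bh_pareto <- function(object, ...) {
  sel <- attr(object, "selected")
  if (length(sel) < 2) {
    p <- ggplot2::ggplot(object,
                         ggplot2::aes(x = .data[[sel[1]]],
                                      y = .data$median_yield,
                                      color = factor(.data$front)))
  } else {
    p <- ggplot2::ggplot(object,
                         ggplot2::aes(x = .data[[sel[1]]],
                                      y = .data[[sel[2]]],
                                      color = factor(.data$front)))
  }
  p + ggplot2::geom_point(ggplot2::aes(size = .data$n_reactions)) +
    ggplot2::scale_color_viridis_d(name = "Pareto front") +
    ggplot2::theme_minimal()
}
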