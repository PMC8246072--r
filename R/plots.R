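# ggplot2 visualizations of SV evidence and evaluation results.

#' Plot simulated vs actual SV evidence for one variant
#'
#' Scatter of realigned alt fraction against the flank-normalized depth
#' fold-change for the simulated per-zygosity training replicates, with the
#' actual observation overlaid — the per-variant view that makes a
#' repetitive-context call interpretable even when no read realigns uniquely
#' to the alternate allele.
#'
#' @param sim_rows Labeled simulated feature tibble for one variant.
#' @param actual_row Optional one-row feature tibble from the actual data.
#' @param x,y Feature names to plot.
#' @return A ggplot object.
#' @export
plot_evidence <- function(sim_rows, actual_row = NULL,
                          x = "alt_fraction", y = "dhffc") {
  p <- ggplot2::ggplot(sim_rows,
                       ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                    colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(HOM_REF = "#d73027", HET = "#4575b4", HOM_ALT = "#1a9850"),
      name = "simulated\nzygosity") +
    ggplot2::labs(x = x, y = y) +
    ggplot2::theme_minimal()
  if (!is.null(actual_row)) {
    p <- p + ggplot2::geom_point(data = actual_row, colour = "black",
                                 shape = 15, size = 3)
  }
  p
}

#' Heatmap of a genotype confusion table
#'
#' @param object A `concordance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.concordance_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$called, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "called genotype", y = "truth genotype") +
    ggplot2::theme_minimal()
}

#' Insert-size distribution of a sample profile
#'
#' @param object A `sample_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sample_profile <- function(object, ...) {
  ggplot2::ggplot(object$insert_pmf,
                  ggplot2::aes(x = .data$len, y = .data$prob)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "fragment length (bp)", y = "probability") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
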