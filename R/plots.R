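#' Plot a kernel density estimate with its mode
#'
#' @param object A [kde()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.prophage_kde <- function(object, ...) {
  mode <- attr(object, "mode")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_vline(xintercept = mode, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "value", y = "density",
                  subtitle = sprintf("mode at %.3g", mode)) +
    ggplot2::theme_minimal()
}

#' Plot the Monte-Carlo dip test
#'
#' Null dip distribution as a histogram with the observed dip marked.
#'
#' @param object A [dip_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dip_test <- function(object, ...) {
  df <- tibble(dip = object$null_dips)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dip)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$dip, colour = "firebrick") +
    ggplot2::labs(x = "dip statistic", y = "null replicates",
                  subtitle = sprintf("observed dip %.4f, p = %.3g",
                                     object$dip, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-bin prophage density against genome size
#'
#' The uniform-density view: mean genomic prophage density per genome-size
#' bin (points sized by bin occupancy), with the cohort mean as a
#' reference line.
#'
#' @param binned Output of [bin_by_genome_size()].
#' @return A ggplot.
#' @export
plot_density_bins <- function(binned) {
  ggplot2::ggplot(binned,
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2e6,
                               y = .data$mean_density)) +
    ggplot2::geom_hline(yintercept = stats::weighted.mean(binned$mean_density,
                                                          binned$n),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), colour = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::labs(x = "host genome size (Mbp)",
                  y = "mean prophage density", size = "genomes") +
    ggplot2::theme_minimal()
}

#' Plot detector regions along a contig
#'
#' Kept and discarded candidate regions as segments, coloured by status.
#'
#' @param regions Detector output for one genome.
#' @return A ggplot.
#' @export
plot_regions <- function(regions) {
  ggplot2::ggplot(regions,
                  ggplot2::aes(x = .data$start / 1e3, xend = .data$end / 1e3,
                               y = .data$contig_id, yend = .data$contig_id,
                               colour = .data$status)) +
    ggplot2::geom_segment(linewidth = 4) +
    ggplot2::scale_colour_manual(values = c(kept = "firebrick",
                                            discarded = "grey60",
                                            pending = "orange")) +
    ggplot2::labs(x = "position (kbp)", y = NULL, colour = "status") +
    ggplot2::theme_minimal()
}
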