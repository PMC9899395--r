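# ggplot2 graphics for result objects.

#' Plot library composition
#'
#' Per-chromosome captured bases, filled by nothing fancy; the subtitle
#' carries the genome-wide coverage and end-pair split.
#'
#' @param object A `gbs_library_prediction`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gbs_library_prediction <- function(object, ...) {
  pairs_lab <- paste(sprintf("%s %.1f%%", object$pairs$pair,
                             100 * object$pairs$proportion), collapse = ", ")
  ggplot2::ggplot(object$per_chromosome,
                  ggplot2::aes(x = .data$chrom, y = .data$captured_bases / 1e3)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "captured (kb)",
      title = sprintf("Predicted library: %.3g%% of the genome captured",
                      object$summary$coverage_percent),
      subtitle = pairs_lab) +
    ggplot2::theme_minimal()
}

#' Plot fragment length distribution
#'
#' Histogram of fragment lengths with the design's size-selection window
#' marked.
#'
#' @param fragments A fragment tibble from [digest()] or
#'   [select_fragments()].
#' @param design Optional [library_design()] whose window is drawn.
#' @param binwidth Histogram bin width in bp.
#' @param max_length Truncate the x axis (default 1000 bp).
#' @return A ggplot.
#' @export
plot_fragment_lengths <- function(fragments, design = NULL, binwidth = 25,
                                  max_length = 1000) {
  dat <- fragments[fragments$width <= max_length, , drop = FALSE]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$width)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::labs(x = "fragment length (bp)", y = "fragments") +
    ggplot2::theme_minimal()
  if (!is.null(design)) {
    p <- p + ggplot2::geom_vline(xintercept = design$size_window,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot a read-budget curve
#'
#' Predicted dropout (missing-data) probability and
#' below-minimum-depth probability against reads per sample.
#'
#' @inheritParams budget_curve
#' @return A ggplot.
#' @export
plot_budget_curve <- function(n_fragments, reads, min_depth = 2) {
  dat <- budget_curve(n_fragments, reads, min_depth = min_depth) |>
    tidyr::pivot_longer(c("dropout_probability", "p_below_min_depth"),
                        names_to = "metric", values_to = "probability")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$reads_per_sample,
                                    y = .data$probability,
                                    colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(labels = function(x) format(x, big.mark = ",")) +
    ggplot2::labs(x = "reads per sample", y = "probability",
                  title = sprintf("Poisson read budget over %s fragments",
                                  format(n_fragments, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Plot marker densities
#'
#' Per-chromosome marker density bars from a `gbs_marker_report`.
#'
#' @param object A `gbs_marker_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gbs_marker_report <- function(object, ...) {
  unit <- if (identical(object$scale, "genetic")) "SNP/cM" else "SNP/Mb"
  ggplot2::ggplot(object$per_chromosome,
                  ggplot2::aes(x = .data$chrom, y = .data$density)) +
    ggplot2::geom_col(fill = "darkgreen") +
    ggplot2::geom_hline(yintercept = object$summary$density,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = unit,
                  title = sprintf("Marker density (genome-wide %.2f %s)",
                                  object$summary$density, unit)) +
    ggplot2::theme_minimal()
}

#' Plot simulated per-fragment depth
#'
#' Histogram of simulated read counts per fragment with the Poisson zero
#' class prediction annotated.
#'
#' @param object A `gbs_read_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gbs_read_sim <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(object$counts, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_bar(fill = "grey40") +
    ggplot2::labs(
      x = "reads per fragment", y = "fragments",
      title = sprintf("Simulated depth (lambda = %.2f)", s$poisson_lambda),
      subtitle = sprintf("zero-count %.3f observed vs %.3f Poisson",
                         s$prop_zero, s$poisson_prop_zero)) +
    ggplot2::theme_minimal()
}
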