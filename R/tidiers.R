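# broom-style tidiers for the package's result objects.

#' Tidy a library prediction
#'
#' @param x A `gbs_library_prediction`.
#' @param ... Unused.
#' @return End-pair composition tibble (`pair`, `n_fragments`,
#'   `proportion`).
#' @export
tidy.gbs_library_prediction <- function(x, ...) x$pairs

#' @rdname tidy.gbs_library_prediction
#' @return `glance()`: the one-row coverage summary.
#' @export
glance.gbs_library_prediction <- function(x, ...) x$summary

#' Tidy a read budget
#'
#' @param x A `gbs_budget`.
#' @param ... Unused.
#' @return One-row budget tibble.
#' @export
tidy.gbs_budget <- function(x, ...) x$summary

#' @rdname tidy.gbs_budget
#' @export
glance.gbs_budget <- function(x, ...) x$summary

#' Tidy a read simulation
#'
#' @param x A `gbs_read_sim`.
#' @param ... Unused.
#' @return Per-fragment counts tibble.
#' @export
tidy.gbs_read_sim <- function(x, ...) x$counts

#' @rdname tidy.gbs_read_sim
#' @export
glance.gbs_read_sim <- function(x, ...) x$summary

#' Tidy a marker report
#'
#' @param x A `gbs_marker_report`.
#' @param ... Unused.
#' @return Per-chromosome density tibble.
#' @export
tidy.gbs_marker_report <- function(x, ...) x$per_chromosome

#' @rdname tidy.gbs_marker_report
#' @return `glance()`: one-row summary with gap counts spread into
#'   `gaps_gt_*` columns.
#' @export
glance.gbs_marker_report <- function(x, ...) {
  out <- x$summary
  for (i in seq_len(nrow(x$gaps))) {
    out[[paste0("gaps_gt_", format(x$gaps$threshold[i], scientific = FALSE))]] <-
      x$gaps$n_gaps[i]
  }
  out
}

#' Tidy diversity statistics
#'
#' @param x A `gbs_diversity`.
#' @param ... Unused.
#' @return Per-site statistics tibble.
#' @export
tidy.gbs_diversity <- function(x, ...) x$per_site

#' @rdname tidy.gbs_diversity
#' @export
glance.gbs_diversity <- function(x, ...) x$summary
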