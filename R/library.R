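# Library selection model: which digestion fragments actually enter a
# sequencing library. A fragment is amplifiable only if its two ends carry
# the overhangs matched by the 5' adapter (one of the rare cutters) and the
# 3' adapter (the frequent cutter), and its length passes size selection.

#' Describe a GBS library design
#'
#' Captures the adapter-compatibility and size-selection model of a
#' multi-enzyme GBS library. The default is the three-enzyme design: the 5'
#' adapter matches the common overhang of the rare cutters PstI and NsiI,
#' the 3' adapter matches the frequent cutter MspI, and size selection keeps
#' 50-350 bp molecules. Setting `rare_set` equal to `frequent_cutter`
#' declares a single-enzyme (ApeKI-style) design in which both fragment
#' ends must carry that enzyme's overhang.
#'
#' @param rare_set Character vector of rare-cutter names matched by the 5'
#'   adapter.
#' @param frequent_cutter Single frequent-cutter name matched by the 3'
#'   adapter.
#' @param size_window Inclusive length window `c(min, max)` in bp applied to
#'   insert length plus `adapter_extension`.
#' @param adapter_extension bp added to the insert length before windowing,
#'   for users who want the window to act on adapter-ligated molecule
#'   length. Default 0 (window on insert length).
#' @return An object of class `gbs_library_design`.
#' @examples
#' library_design()
#' library_design(rare_set = "ApeKI", frequent_cutter = "ApeKI")
#' @export
library_design <- function(rare_set = c("PstI", "NsiI"), frequent_cutter = "MspI",
                           size_window = c(50, 350), adapter_extension = 0) {
  if (length(frequent_cutter) != 1L) {
    abort("`frequent_cutter` must be a single enzyme name.", class = "gbs_bad_design")
  }
  single <- length(rare_set) == 1L && identical(rare_set, frequent_cutter)
  if (!single && frequent_cutter %in% rare_set) {
    abort("`rare_set` and `frequent_cutter` must be disjoint (or identical for a single-enzyme design).",
          class = "gbs_bad_design")
  }
  if (length(size_window) != 2L || size_window[1] < 1 || size_window[1] > size_window[2]) {
    abort("`size_window` must be c(min, max) with 1 <= min <= max.",
          class = "gbs_bad_design")
  }
  structure(
    list(rare_set = rare_set, frequent_cutter = frequent_cutter,
         size_window = as.numeric(size_window),
         adapter_extension = as.numeric(adapter_extension),
         single_enzyme = single),
    class = "gbs_library_design"
  )
}

#' @export
print.gbs_library_design <- function(x, ...) {
  cat("<gbs_library_design>\n")
  if (x$single_enzyme) {
    cat("  single-enzyme design:", x$frequent_cutter, "\n")
  } else {
    cat("  rare set (5' adapter):", paste(x$rare_set, collapse = ", "), "\n")
    cat("  frequent cutter (3' adapter):", x$frequent_cutter, "\n")
  }
  cat(sprintf("  size window: [%g, %g] bp (adapter extension %g bp)\n",
              x$size_window[1], x$size_window[2], x$adapter_extension))
  invisible(x)
}

check_design_enzymes <- function(design, fragments) {
  known <- unique(c(gbs_enzymes()$name, fragments$left, fragments$right))
  missing <- setdiff(c(design$rare_set, design$frequent_cutter), known)
  if (length(missing) > 0) {
    abort(sprintf("Design references unknown enzyme(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "gbs_unknown_enzyme")
  }
}

#' Select library-compatible fragments
#'
#' Retains the fragments that would receive both adapters and survive size
#' selection: one end labelled by a rare-set enzyme, the other by the
#' frequent cutter (either orientation), and insert length plus adapter
#' extension inside the size window. Fragments with a sequence-terminus
#' end, rare-rare, frequent-frequent, or rare-rare pairs across the rare
#' set are excluded. For a single-enzyme design both ends must match that
#' enzyme.
#'
#' @param fragments A fragment tibble from [digest()].
#' @param design A [library_design()].
#' @return The selected fragments with an added `pair` column
#'   (`"Rare-Frequent"` label, rare cutter first).
#' @export
select_fragments <- function(fragments, design = library_design()) {
  stopifnot(inherits(design, "gbs_library_design"))
  check_design_enzymes(design, fragments)
  len <- fragments$width + design$adapter_extension
  in_window <- len >= design$size_window[1] & len <= design$size_window[2]
  if (design$single_enzyme) {
    e <- design$frequent_cutter
    compatible <- fragments$left == e & fragments$right == e
    pair <- paste0(e, "-", e)
  } else {
    lr <- fragments$left %in% design$rare_set & fragments$right == design$frequent_cutter
    rl <- fragments$right %in% design$rare_set & fragments$left == design$frequent_cutter
    compatible <- lr | rl
    rare_end <- ifelse(lr, fragments$left, fragments$right)
    pair <- paste0(rare_end, "-", design$frequent_cutter)
  }
  out <- fragments[compatible & in_window, , drop = FALSE]
  out$pair <- pair[compatible & in_window]
  tibble::as_tibble(out)
}

#' Predict library composition and genome coverage
#'
#' Applies [select_fragments()] and summarizes the predicted library: number
#' of selected fragments, captured bases, genome coverage fraction
#' (captured / genome length), per-sequence breakdown, and the proportion of
#' fragments contributed by each rare-frequent end pair (the PstI-MspI vs
#' NsiI-MspI split of a three-enzyme design).
#'
#' @inheritParams select_fragments
#' @param genome_length Total genome length in bp.
#' @return A `gbs_library_prediction` object; see [tidy()] (pair
#'   proportions), [glance()] (one-row summary), and [autoplot()].
#' @export
predict_library <- function(fragments, design = library_design(), genome_length) {
  check_positive_scalar(genome_length, "genome_length")
  selected <- select_fragments(fragments, design)
  summary <- tibble::tibble(
    n_selected = nrow(selected),
    captured_bases = sum(selected$width),
    genome_length = genome_length,
    coverage_fraction = sum(selected$width) / genome_length,
    coverage_percent = 100 * sum(selected$width) / genome_length
  )
  per_chromosome <- selected |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(n_fragments = dplyr::n(),
                     captured_bases = sum(.data$width), .groups = "drop")
  pairs <- selected |>
    dplyr::group_by(pair = .data$pair) |>
    dplyr::summarise(n_fragments = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(proportion = .data$n_fragments / sum(.data$n_fragments))
  structure(
    list(summary = summary, per_chromosome = per_chromosome, pairs = pairs,
         selected = selected, design = design),
    class = "gbs_library_prediction"
  )
}

#' @export
print.gbs_library_prediction <- function(x, ...) {
  s <- x$summary
  cat("<gbs_library_prediction>\n")
  cat(sprintf("  %d fragments selected, %s bp captured (%.3g%% of %s bp)\n",
              s$n_selected, format(s$captured_bases, big.mark = ","),
              s$coverage_percent, format(s$genome_length, big.mark = ",")))
  if (nrow(x$pairs) > 0) {
    cat("  end-pair composition:\n")
    for (i in seq_len(nrow(x$pairs))) {
      cat(sprintf("    %s: %d (%.1f%%)\n", x$pairs$pair[i],
                  x$pairs$n_fragments[i], 100 * x$pairs$proportion[i]))
    }
  }
  invisible(x)
}
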