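# Read-budget arithmetic: per-fragment depth, genotype dropout and
# multiplex capacity under a Poisson read-allocation model, plus the
# whole-genome-sequencing depth and cost-reduction formulas used to compare
# designs.

#' Read budget for a reduced-representation library
#'
#' Models the allocation of `reads_per_sample` single-end reads across `F`
#' selected fragments as Poisson with per-fragment mean
#' `lambda = reads_per_sample / n_fragments`. Reports the expected dropout
#' probability `exp(-lambda)` (fraction of fragments receiving no read,
#' i.e. predicted missing data), the probability a fragment receives fewer
#' than `min_depth` reads, and the number of samples that fit on a run of
#' `run_capacity` reads. Alternatively, give `target_depth` to solve the
#' inverse problem: the smallest read count achieving that per-fragment
#' depth.
#'
#' @param n_fragments Number of selected fragments (`F > 0`).
#' @param reads_per_sample Reads allocated to one sample. Omit if
#'   `target_depth` is given.
#' @param target_depth Desired per-fragment mean depth; sets
#'   `reads_per_sample = ceiling(target_depth * n_fragments)`.
#' @param min_depth Minimum depth for a confident genotype call (default 2).
#' @param run_capacity Optional total reads per sequencing run, for the
#'   multiplex-capacity calculation.
#' @return A `gbs_budget` object (one-row tibble via [glance()]).
#' @examples
#' gbs_budget(n_fragments = 20000, reads_per_sample = 200000, run_capacity = 8e7)
#' gbs_budget(n_fragments = 20000, target_depth = 5)
#' @export
gbs_budget <- function(n_fragments, reads_per_sample = NULL, target_depth = NULL,
                       min_depth = 2, run_capacity = NULL) {
  check_positive_scalar(n_fragments, "n_fragments")
  if (is.null(reads_per_sample)) {
    if (is.null(target_depth)) {
      abort("Give either `reads_per_sample` or `target_depth`.",
            class = "gbs_bad_argument")
    }
    reads_per_sample <- ceiling(target_depth * n_fragments)
  }
  if (reads_per_sample < 0) {
    abort("`reads_per_sample` must be non-negative.", class = "gbs_bad_argument")
  }
  lambda <- reads_per_sample / n_fragments
  res <- tibble::tibble(
    n_fragments = n_fragments,
    reads_per_sample = reads_per_sample,
    lambda = lambda,
    dropout_probability = exp(-lambda),
    min_depth = min_depth,
    p_below_min_depth = ppois(min_depth - 1, lambda),
    run_capacity = run_capacity %||% NA_real_,
    multiplex_capacity = if (is.null(run_capacity) || reads_per_sample == 0) {
      NA_integer_
    } else {
      as.integer(floor(run_capacity / reads_per_sample))
    }
  )
  structure(list(summary = res), class = "gbs_budget")
}

#' @export
print.gbs_budget <- function(x, ...) {
  s <- x$summary
  cat("<gbs_budget>\n")
  cat(sprintf("  %s reads over %s fragments -> lambda = %.3g reads/fragment\n",
              format(s$reads_per_sample, big.mark = ","),
              format(s$n_fragments, big.mark = ","), s$lambda))
  cat(sprintf("  dropout P(depth = 0) = %.3g; P(depth < %d) = %.3g\n",
              s$dropout_probability, s$min_depth, s$p_below_min_depth))
  if (!is.na(s$multiplex_capacity)) {
    cat(sprintf("  multiplex capacity at %s reads/run: %d samples\n",
                format(s$run_capacity, big.mark = ","), s$multiplex_capacity))
  }
  invisible(x)
}

#' Reads needed for a target per-fragment depth
#'
#' @inheritParams gbs_budget
#' @return Integer read count `ceiling(target_depth * n_fragments)`.
#' @export
reads_for_depth <- function(n_fragments, target_depth) {
  check_positive_scalar(n_fragments, "n_fragments")
  ceiling(target_depth * n_fragments)
}

#' Mean depth of whole-genome shotgun sequencing
#'
#' The fold coverage `reads * read_length / genome_length` of unselected
#' (skim) sequencing, the baseline against which fragment-focused designs
#' are compared: 1M reads of 100 bp give 0.1X on a 1 Gb genome.
#'
#' @param reads Number of reads.
#' @param read_length Read length in bp.
#' @param genome_length Genome length in bp.
#' @return Fold coverage (X).
#' @examples
#' wgs_depth(1e6, 100, 1e9)
#' @export
wgs_depth <- function(reads, read_length, genome_length) {
  check_positive_scalar(read_length, "read_length")
  check_positive_scalar(genome_length, "genome_length")
  if (reads < 0) abort("`reads` must be non-negative.", class = "gbs_bad_argument")
  reads * read_length / genome_length
}

#' Percent reduction in per-sample read budget
#'
#' `round(100 * (1 - new/old))`, with halves rounded away from zero, the
#' convention behind headline cost-reduction figures such as "~92% (1.2M vs
#' 100K reads/sample)".
#'
#' @param old_reads Baseline reads per sample (> 0).
#' @param new_reads Reduced reads per sample.
#' @return Integer percentage.
#' @examples
#' percent_reduction(1200000, 100000)  # 92
#' percent_reduction(1400000, 200000)  # 86
#' @export
percent_reduction <- function(old_reads, new_reads) {
  if (any(old_reads <= 0)) {
    abort("`old_reads` must be positive.", class = "gbs_bad_argument")
  }
  as.integer(round_half_up(100 * (1 - new_reads / old_reads)))
}

#' Budget curve over a range of read counts
#'
#' Evaluates the Poisson budget model across a vector of per-sample read
#' counts; convenient for plotting predicted missing data against
#' sequencing effort.
#'
#' @inheritParams gbs_budget
#' @param reads Vector of per-sample read counts.
#' @return A tibble with one row per read count.
#' @export
budget_curve <- function(n_fragments, reads, min_depth = 2, run_capacity = NULL) {
  purrr::map(reads, function(n) {
    glance(gbs_budget(n_fragments, reads_per_sample = n, min_depth = min_depth,
                      run_capacity = run_capacity))
  }) |> dplyr::bind_rows()
}
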