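# Forward read simulation over selected fragments and seeded FASTQ
# subsampling (the in-silico analogue of downsampling a sequenced library
# to 50K-300K reads per sample).

#' Simulate read allocation over selected fragments
#'
#' Draws per-fragment capture weights (uniform when `bias_dispersion = 0`,
#' otherwise log-normal with sdlog `bias_dispersion`, renormalized) and
#' allocates `reads` reads by a single multinomial draw. This is the exact
#' finite-read counterpart of the Poisson budget model and is used to check
#' its dropout predictions.
#'
#' @param selected A selected-fragment tibble from [select_fragments()], or
#'   a single integer fragment count.
#' @param reads Number of reads to allocate (`>= 0`).
#' @param bias_dispersion Non-negative sdlog of the log-normal fragment
#'   weight distribution; 0 means equal capture probability.
#' @param min_depth Depth threshold for the summary's
#'   `prop_below_min_depth`.
#' @param seed Optional integer seed; identical seeds give identical counts.
#' @return A `gbs_read_sim` object: [tidy()] returns per-fragment counts,
#'   [glance()] the summary (mean depth, zero-count fraction, fraction
#'   below `min_depth`, and the Poisson predictions).
#' @export
simulate_reads <- function(selected, reads, bias_dispersion = 0, min_depth = 2,
                           seed = NULL) {
  if (is.numeric(selected) && length(selected) == 1L) {
    frags <- tibble::tibble(fragment = seq_len(selected))
  } else {
    frags <- tibble::as_tibble(selected)
    frags$fragment <- seq_len(nrow(frags))
  }
  n_frag <- nrow(frags)
  if (n_frag == 0) abort("No fragments to simulate.", class = "gbs_bad_argument")
  if (reads < 0) abort("`reads` must be non-negative.", class = "gbs_bad_argument")
  if (bias_dispersion < 0) {
    abort("`bias_dispersion` must be non-negative.", class = "gbs_bad_argument")
  }
  sim <- with_seed_if(seed, {
    w <- if (bias_dispersion == 0) rep(1, n_frag) else rlnorm(n_frag, 0, bias_dispersion)
    w <- w / sum(w)
    counts <- as.integer(rmultinom(1, size = reads, prob = w)[, 1])
    list(w = w, counts = counts)
  })
  frags$weight <- sim$w
  frags$count <- sim$counts
  lambda <- reads / n_frag
  summary <- tibble::tibble(
    reads = reads,
    n_fragments = n_frag,
    bias_dispersion = bias_dispersion,
    mean_depth = mean(sim$counts),
    prop_zero = mean(sim$counts == 0),
    prop_below_min_depth = mean(sim$counts < min_depth),
    min_depth = min_depth,
    poisson_lambda = lambda,
    poisson_prop_zero = exp(-lambda),
    poisson_prop_below_min_depth = ppois(min_depth - 1, lambda)
  )
  structure(list(counts = frags, summary = summary), class = "gbs_read_sim")
}

#' @export
print.gbs_read_sim <- function(x, ...) {
  s <- x$summary
  cat("<gbs_read_sim>\n")
  cat(sprintf("  %s reads over %s fragments (dispersion %g)\n",
              format(s$reads, big.mark = ","),
              format(s$n_fragments, big.mark = ","), s$bias_dispersion))
  cat(sprintf("  mean depth %.3g; zero-count %.3g (Poisson %.3g); below %d: %.3g\n",
              s$mean_depth, s$prop_zero, s$poisson_prop_zero,
              s$min_depth, s$prop_below_min_depth))
  invisible(x)
}

read_fastq_records <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    abort(sprintf("Malformed FASTQ '%s': %d lines is not a multiple of 4.",
                  path, length(lines)),
          class = "gbs_fastq_parse_error")
  }
  n <- length(lines) %/% 4
  if (n > 0) {
    head_idx <- seq(1, length(lines), by = 4)
    plus_idx <- head_idx + 2
    bad <- which(!startsWith(lines[head_idx], "@") | !startsWith(lines[plus_idx], "+"))
    if (length(bad) > 0) {
      abort(sprintf("Malformed FASTQ record %d in '%s'.", bad[1], path),
            class = "gbs_fastq_parse_error")
    }
    bad_len <- which(nchar(lines[head_idx + 1]) != nchar(lines[plus_idx + 1]))
    if (length(bad_len) > 0) {
      abort(sprintf("FASTQ record %d in '%s': sequence/quality length mismatch.",
                    bad_len[1], path),
            class = "gbs_fastq_parse_error")
    }
  }
  list(lines = lines, n = n)
}

#' Subsample a FASTQ file without replacement
#'
#' Draws a uniform, order-preserving sample of `k` records (all records if
#' `k` exceeds the file size). Identical `(input, k, seed)` give
#' byte-identical output, making downsampling replicates reproducible.
#'
#' @param input Path to a FASTQ file (plain text).
#' @param k Number of records to keep (`>= 0`).
#' @param seed Optional integer seed.
#' @param output Optional output path; when `NULL` the sampled records are
#'   returned as a character vector of lines.
#' @return `output` invisibly when writing, otherwise the sampled lines.
#' @export
subsample_fastq <- function(input, k, seed = NULL, output = NULL) {
  if (k < 0) abort("`k` must be non-negative.", class = "gbs_bad_argument")
  fq <- read_fastq_records(input)
  keep_n <- min(k, fq$n)
  idx <- if (keep_n == fq$n) {
    seq_len(fq$n)
  } else {
    sort(with_seed_if(seed, sample.int(fq$n, keep_n)))
  }
  line_idx <- as.vector(vapply(idx, function(i) (i - 1L) * 4L + 1:4, integer(4)))
  out_lines <- fq$lines[line_idx]
  if (is.null(output)) {
    out_lines
  } else {
    writeLines(out_lines, output)
    invisible(output)
  }
}
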