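# Genotype-level diversity statistics and identity-by-state distances on
# filtered variant records.

split_alleles <- function(gt) {
  # genotype matrix -> two character allele matrices (NA preserved)
  a1 <- gt; a2 <- gt
  nz <- !is.na(gt)
  parts <- strsplit(gt[nz], "[/|]")
  a1[nz] <- vapply(parts, `[`, character(1), 1)
  a2[nz] <- vapply(parts, function(x) if (length(x) >= 2) x[2] else x[1],
                   character(1))
  list(a1 = a1, a2 = a2)
}

#' Diversity statistics of a marker set
#'
#' Computes, over a set of (typically filtered, biallelic) variant records:
#' the overall fraction of missing genotype calls, the heterozygous
#' fraction among non-missing calls, per-site minor allele frequency from
#' allele counts, and per-site nucleotide diversity
#' `pi = 2 p (1 - p) n / (n - 1)` with `n` the number of non-missing
#' alleles (the unbiased per-site expected-heterozygosity estimator).
#' Sites with no non-missing call contribute to the missing fraction but
#' are skipped for MAF and pi.
#'
#' @param records A variant tibble with a genotype matrix column `gt`
#'   (at least 2 samples).
#' @return A `gbs_diversity` object: [tidy()] returns the per-site table
#'   (`site`, `n_alleles`, `het_rate`, `maf`, `pi`), [glance()] the
#'   genome-wide summary.
#' @export
diversity_stats <- function(records) {
  gt <- records$gt
  if (nrow(records) < 1 || ncol(gt) < 2) {
    abort("Need at least one record and two samples.", class = "gbs_bad_argument")
  }
  al <- split_alleles(gt)
  n_sites <- nrow(records)
  per_site <- purrr::map(seq_len(n_sites), function(i) {
    a <- c(al$a1[i, ], al$a2[i, ])
    a <- a[!is.na(a)]
    g <- gt[i, ]
    if (length(a) == 0) {
      return(tibble::tibble(site = records$id[i], n_alleles = 0L,
                            het_rate = NA_real_, maf = NA_real_, pi = NA_real_))
    }
    counts <- table(a)
    p_major <- max(counts) / length(a)
    maf <- 1 - p_major
    # expected heterozygosity generalized to >2 alleles: 1 - sum p_k^2
    p_k <- as.numeric(counts) / length(a)
    het_exp <- 1 - sum(p_k^2)
    n <- length(a)
    pi <- if (n > 1) het_exp * n / (n - 1) else NA_real_
    tibble::tibble(site = records$id[i], n_alleles = n,
                   het_rate = site_het_rate(g), maf = maf, pi = pi)
  }) |> dplyr::bind_rows()

  n_skipped <- sum(per_site$n_alleles == 0)
  if (n_skipped > 0) {
    inform(sprintf("%d all-missing site(s) skipped for MAF/pi.", n_skipped))
  }
  n_missing_calls <- sum(is.na(gt))
  n_calls <- length(gt)
  non_missing <- gt[!is.na(gt)]
  het_calls <- vapply(strsplit(non_missing, "[/|]"),
                      function(x) x[1] != x[2], logical(1))
  summary <- tibble::tibble(
    n_sites = n_sites,
    n_samples = ncol(gt),
    prop_missing = n_missing_calls / n_calls,
    prop_het = if (length(het_calls) > 0) mean(het_calls) else NA_real_,
    mean_maf = mean(per_site$maf, na.rm = TRUE),
    mean_pi = mean(per_site$pi, na.rm = TRUE)
  )
  structure(list(per_site = per_site, summary = summary),
            class = "gbs_diversity")
}

#' @export
print.gbs_diversity <- function(x, ...) {
  s <- x$summary
  cat("<gbs_diversity>\n")
  cat(sprintf("  %d sites x %d samples\n", s$n_sites, s$n_samples))
  cat(sprintf("  missing %.1f%%; het %.1f%%; mean MAF %.3f; mean pi %.3f\n",
              100 * s$prop_missing, 100 * s$prop_het, s$mean_maf, s$mean_pi))
  invisible(x)
}

# shared alleles between two diploid genotypes = multiset intersection size
# of their allele pairs; for 2-element multisets this equals the best of
# the two pairings.
shared_allele_matrix <- function(a1x, a2x, a1y, a2y) {
  direct <- (a1x == a1y) + (a2x == a2y)
  crossed <- (a1x == a2y) + (a2x == a1y)
  pmax(direct, crossed)
}

#' Identity-by-state distance matrix
#'
#' Pairwise IBS distance between samples:
#' `1 - mean(shared alleles / 2)` over sites where both samples have a
#' call. Diagonal 0, symmetric; a pair with no comparable site gets `NA`.
#'
#' @param records A variant tibble with genotype matrix column `gt` (at
#'   least 2 samples).
#' @return A symmetric numeric matrix with sample dimnames.
#' @export
ibs_distance_matrix <- function(records) {
  gt <- records$gt
  if (ncol(gt) < 2) abort("Need at least two samples.", class = "gbs_bad_argument")
  al <- split_alleles(gt)
  samples <- colnames(gt)
  ns <- length(samples)
  d <- matrix(0, ns, ns, dimnames = list(samples, samples))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      ok <- !is.na(gt[, i]) & !is.na(gt[, j])
      if (!any(ok)) {
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      shared <- shared_allele_matrix(al$a1[ok, i], al$a2[ok, i],
                                     al$a1[ok, j], al$a2[ok, j])
      d[i, j] <- d[j, i] <- 1 - mean(shared) / 2
    }
  }
  d
}

#' Polymorphic marker count between two samples
#'
#' Number of sites at which both samples have a genotype call and the
#' (unordered) genotypes differ - the marker yield available to a
#' biparental cross between the two samples. Densities per Mb / per cM are
#' reported when the corresponding total spans are supplied.
#'
#' @param records A variant tibble with genotype matrix column `gt`.
#' @param sample_a,sample_b Sample names (columns of `gt`).
#' @param genome_length Optional total genome length in bp for SNP/Mb.
#' @param map_length_cM Optional total map length in cM for SNP/cM.
#' @return One-row tibble: `sample_a`, `sample_b`, `n_comparable`,
#'   `n_polymorphic`, `per_mb`, `per_cm`.
#' @export
count_polymorphic_pair <- function(records, sample_a, sample_b,
                                   genome_length = NULL, map_length_cM = NULL) {
  gt <- records$gt
  missing <- setdiff(c(sample_a, sample_b), colnames(gt))
  if (length(missing) > 0) {
    abort(sprintf("Unknown sample(s): %s.", paste(missing, collapse = ", ")),
          class = "gbs_unknown_sample")
  }
  ga <- gt[, sample_a]
  gb <- gt[, sample_b]
  ok <- !is.na(ga) & !is.na(gb)
  norm <- function(g) {
    vapply(strsplit(g, "[/|]"),
           function(x) paste(sort(x), collapse = "/"), character(1))
  }
  differ <- ok
  differ[ok] <- norm(ga[ok]) != norm(gb[ok])
  n_poly <- sum(differ)
  tibble::tibble(
    sample_a = sample_a, sample_b = sample_b,
    n_comparable = sum(ok), n_polymorphic = n_poly,
    per_mb = if (is.null(genome_length)) NA_real_ else n_poly / (genome_length / 1e6),
    per_cm = if (is.null(map_length_cM)) NA_real_ else n_poly / map_length_cM
  )
}
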