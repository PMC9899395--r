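# Diversity statistics, IBS distances, and pairwise polymorphism counts.

records_from_gt <- function(gt_mat) {
  n <- nrow(gt_mat)
  rec <- tibble::tibble(chrom = "Chr01", pos = seq_len(n) * 100L,
                        id = sprintf("s%03d", seq_len(n)),
                        ref = "A", alt = "T", qual = 50, mq = 60)
  rec$gt <- gt_mat
  rec
}

gt_matrix <- function(..., samples = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- samples %||% sprintf("S%02d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("monomorphic data give zero heterozygosity, MAF and pi", {
  rec <- records_from_gt(gt_matrix(c("0/0", "0/0", "0/0"),
                                   c("0/0", "0/0", "0/0")))
  d <- diversity_stats(rec)
  s <- glance(d)
  expect_equal(s$prop_het, 0)
  expect_equal(s$mean_maf, 0)
  expect_equal(s$mean_pi, 0)
  expect_equal(s$prop_missing, 0)
})

test_that("pi uses the unbiased per-site estimator", {
  # one site, two samples, AA and TT: p = 0.5, n = 4 alleles
  rec <- records_from_gt(gt_matrix(c("0/0", "1/1")))
  d <- tidy(diversity_stats(rec))
  expect_equal(d$maf, 0.5)
  expect_equal(d$pi, 2 * 0.25 * (4 / 3))
})

test_that("missing and heterozygous fractions are counted over calls", {
  rec <- records_from_gt(gt_matrix(c("0/0", "0/1", NA, "1/1"),
                                   c(NA, NA, "0/1", "0/0")))
  s <- glance(suppressMessages(diversity_stats(rec)))
  expect_equal(s$prop_missing, 3 / 8)
  expect_equal(s$prop_het, 2 / 5)
})

test_that("all-missing sites are skipped for MAF and pi with a message", {
  rec <- records_from_gt(gt_matrix(c(NA, NA), c("0/0", "1/1")))
  expect_message(d <- diversity_stats(rec), "all-missing")
  expect_true(is.na(tidy(d)$maf[1]))
  expect_equal(tidy(d)$maf[2], 0.5)
})

test_that("generator allele frequencies are recovered", {
  v <- make_vcf(n_samples = 40, n_sites = 400,
                chrom_lengths = c(Chr01 = 1e7),
                qual = 50, mq = 60, missing_rate = 0, het_rate = 0,
                maf = 0.3, frac_indel = 0, frac_multiallelic = 0, seed = 17)
  d <- glance(diversity_stats(v$records))
  # sites drift around p = 0.3; minor-allele folding keeps MAF <= 0.5
  expect_lt(abs(d$mean_maf - 0.3), 0.03)
  expect_equal(d$prop_missing, 0)
})

test_that("IBS distance matches shared-allele enumeration", {
  rec <- records_from_gt(gt_matrix(c("0/0", "1/1", "0/0"),
                                   c("0/0", "1/1", "0/1"),
                                   c("0/0", "1/1", "1/1"),
                                   c("0/1", "1/0", "0/1")))
  d <- ibs_distance_matrix(rec)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))
  # S1 vs S2: identical at all four sites -> 0... except site 4 het order
  expect_equal(d["S01", "S02"], brute_ibs(rec$gt[, "S01"], rec$gt[, "S02"]))
  # AA vs TT at every site -> distance 1
  far <- records_from_gt(gt_matrix(c("0/0", "1/1"), c("0/0", "1/1")))
  expect_equal(far[["gt"]][1, ], c(S01 = "0/0", S02 = "1/1"))
  expect_equal(ibs_distance_matrix(far)["S01", "S02"], 1)
  # AA vs AT -> 0.5 per site
  half <- records_from_gt(gt_matrix(c("0/0", "0/1")))
  expect_equal(ibs_distance_matrix(half)["S01", "S02"], 0.5)
})

test_that("IBS is a pseudometric on random genotype fixtures", {
  withr::with_seed(55, {
    for (i in 1:3) {
      gt <- matrix(sample(c("0/0", "0/1", "1/1", NA), 50 * 6, replace = TRUE,
                          prob = c(0.4, 0.2, 0.3, 0.1)),
                   nrow = 50, dimnames = list(NULL, sprintf("S%02d", 1:6)))
      rec <- records_from_gt(gt)
      d <- ibs_distance_matrix(rec)
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
      expect_true(all(d >= 0 & d <= 1, na.rm = TRUE))
      # brute-force agreement on all pairs
      for (a in 1:5) for (b in (a + 1):6) {
        expect_equal(d[a, b], brute_ibs(gt[, a], gt[, b]))
      }
      # triangle inequality
      for (a in 1:6) for (b in 1:6) for (cc in 1:6) {
        if (!anyNA(c(d[a, b], d[b, cc], d[a, cc]))) {
          expect_lte(d[a, cc], d[a, b] + d[b, cc] + 1e-12)
        }
      }
    }
  })
})

test_that("pairs with no comparable site are NA, not zero", {
  rec <- records_from_gt(gt_matrix(c("0/0", NA), c(NA, "1/1")))
  d <- ibs_distance_matrix(rec)
  expect_true(is.na(d["S01", "S02"]))
})

test_that("polymorphic pair counts discordant comparable sites", {
  gt <- gt_matrix(
    c("0/0", "1/1"), c("0/0", "1/1"), c("0/0", "1/1"), c("0/1", "1/1"),
    c("0/0", "0/1"), c("0/1", "0/0"), c("1/1", "0/0"),          # 7 discordant
    c("0/0", "0/0"), c("1/1", "1/1"), c("0/1", "1/0"),          # 3 concordant
    c(NA, "0/0"), c("0/0", NA)                                  # 2 half-missing
  )
  rec <- records_from_gt(gt)
  res <- count_polymorphic_pair(rec, "S01", "S02",
                                genome_length = 1e6, map_length_cM = 50)
  expect_equal(res$n_polymorphic, 7L)
  expect_equal(res$n_comparable, 10L)
  expect_equal(res$per_mb, 7)
  expect_equal(res$per_cm, 7 / 50)
  same <- count_polymorphic_pair(rec, "S01", "S01")
  expect_equal(same$n_polymorphic, 0L)
  expect_error(count_polymorphic_pair(rec, "S01", "S99"),
               class = "gbs_unknown_sample")
})

test_that("most distant pair by IBS has the most polymorphisms when all calls are homozygous", {
  withr::with_seed(77, {
    gt <- matrix(sample(c("0/0", "1/1"), 80 * 5, replace = TRUE),
                 nrow = 80, dimnames = list(NULL, sprintf("S%02d", 1:5)))
    rec <- records_from_gt(gt)
    d <- ibs_distance_matrix(rec)
    pairs <- t(utils::combn(colnames(gt), 2))
    poly <- apply(pairs, 1, function(p) {
      count_polymorphic_pair(rec, p[1], p[2])$n_polymorphic
    })
    dist <- apply(pairs, 1, function(p) d[p[1], p[2]])
    expect_equal(which.max(poly), which.max(dist))
  })
})
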