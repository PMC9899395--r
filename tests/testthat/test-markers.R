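# Variant filtering and marker-distribution diagnostics.

make_record <- function(qual = 50, mq = 40, chrom = "Chr01", ref = "A",
                        alt = "T", gt = c("0/0", "0/1", "1/1", "0/0", "0/0")) {
  rec <- tibble::tibble(chrom = chrom, pos = 100L, id = "s1", ref = ref,
                        alt = alt, qual = qual, mq = mq)
  rec$gt <- matrix(gt, nrow = 1,
                   dimnames = list(NULL, sprintf("S%02d", seq_along(gt))))
  rec
}

test_that("filters remove records for the stated reasons in order", {
  gt10 <- c(rep("0/0", 7), "0/1", NA, NA)  # 20% missing, 1/8 het
  keep <- make_record(gt = c(rep("0/0", 19), "0/1"))  # 5% het, 0 missing
  expect_true(filter_variants(keep)$pass)

  expect_equal(filter_variants(make_record(qual = 5))$reason, "low_qual")
  expect_equal(filter_variants(make_record(mq = 20))$reason, "low_mq")
  expect_equal(filter_variants(make_record(mq = NA))$reason, "low_mq")
  expect_equal(filter_variants(make_record(chrom = "scaffold_3"))$reason, "scaffold")
  expect_equal(filter_variants(make_record(alt = "TA"))$reason, "indel")
  expect_equal(filter_variants(make_record(ref = "AT"))$reason, "indel")
  expect_equal(filter_variants(make_record(alt = "T,G"))$reason, "multiallelic")
  expect_equal(filter_variants(make_record(gt = c(NA, NA, NA, NA, "0/0")))$reason,
               "missing")
  expect_equal(filter_variants(make_record(gt = c("0/1", "0/0", rep("0/0", 8))))$reason,
               "het")
  # first failing rule wins
  expect_equal(filter_variants(make_record(qual = 5, chrom = "scaffold_1",
                                           alt = "TA"))$reason, "low_qual")
})

test_that("retention thresholds are strict inequalities", {
  # missing rate exactly 0.8 -> removed
  rec <- make_record(gt = c(NA, NA, NA, NA, "0/0"))
  expect_equal(filter_variants(rec)$reason, "missing")
  # missing rate 0.75 -> kept
  rec2 <- make_record(gt = c(NA, NA, NA, "0/0"))
  expect_true(filter_variants(rec2)$pass)
  # het rate exactly 0.1 -> removed; just below -> kept
  rec3 <- make_record(gt = c("0/1", rep("0/0", 9)))
  expect_equal(filter_variants(rec3)$reason, "het")
  rec4 <- make_record(gt = c("0/1", rep("0/0", 10)))
  expect_true(filter_variants(rec4)$pass)
})

test_that("QUAL/MQ removal rule is configurable", {
  gt_ok <- rep("0/0", 10)
  rec <- make_record(qual = 5, mq = 60, gt = gt_ok)
  expect_false(filter_variants(rec)$pass)
  expect_true(filter_variants(rec, filter_config(qual_mq_rule = "both"))$pass)
  rec2 <- make_record(qual = 5, mq = 5, gt = gt_ok)
  expect_false(filter_variants(rec2, filter_config(qual_mq_rule = "both"))$pass)
})

test_that("filtering reproduces the generator's constructive truth", {
  v <- make_vcf(n_samples = 12, n_sites = 500, seed = 13)
  res <- filter_variants(v$records)
  expect_identical(res$pass, v$truth$pass)
  expect_identical(res$reason, v$truth$reason)
})

test_that("tightening a threshold retains a subset", {
  v <- make_vcf(n_samples = 10, n_sites = 300, seed = 14)
  base <- filter_variants(v$records, filter_config())
  kept_base <- base$id[base$pass]
  for (cfg in list(filter_config(min_qual = 30),
                   filter_config(min_mq = 50),
                   filter_config(max_missing_rate = 0.4),
                   filter_config(max_het_rate = 0.05))) {
    tight <- filter_variants(v$records, cfg)
    expect_true(all(tight$id[tight$pass] %in% kept_base))
  }
})

test_that("physical gap inventory matches hand arithmetic", {
  markers <- tibble::tibble(chrom = "Chr01", pos = c(100, 11000100))
  rep <- density_and_gaps(markers, c(Chr01 = 2e7))
  expect_equal(rep$gaps$n_gaps, c(1L, 1L))  # 11 Mb gap exceeds 5 and 10 Mb
  expect_equal(rep$gaps$gaps[[1]]$width, 11e6)

  single <- density_and_gaps(tibble::tibble(chrom = "Chr01", pos = 5),
                             c(Chr01 = 2e7))
  expect_equal(single$gaps$n_gaps, c(0L, 0L))

  # chromosome ends only count when requested
  ends <- density_and_gaps(tibble::tibble(chrom = "Chr01", pos = 1e7),
                           c(Chr01 = 3e7), include_ends = TRUE)
  expect_equal(ends$gaps$n_gaps, c(2L, 1L))

  expect_error(density_and_gaps(tibble::tibble(chrom = "Chr01", pos = 3e7 + 1),
                                c(Chr01 = 3e7)),
               class = "gbs_bad_argument")
})

test_that("densities use total span in the right unit", {
  markers <- tibble::tibble(chrom = rep(c("Chr01", "Chr02"), c(60, 40)),
                            pos = c(seq_len(60) * 1e5, seq_len(40) * 1e5))
  rep <- density_and_gaps(markers, c(Chr01 = 1e7, Chr02 = 1e7))
  expect_equal(glance(rep)$density, 100 / 20)  # SNP/Mb
  expect_equal(tidy(rep)$density, c(6, 4))
})

test_that("gap counts match a brute-force scan on random markers", {
  withr::with_seed(99, {
    for (rep_i in 1:5) {
      pos <- sort(sample.int(5e7, 200))
      chrom <- sample(c("Chr01", "Chr02"), 200, replace = TRUE)
      markers <- tibble::tibble(chrom = chrom, pos = pos)
      r <- density_and_gaps(markers, c(Chr01 = 5e7, Chr02 = 5e7),
                            thresholds = c(1e5, 5e5, 1e6))
      split_pos <- split(markers$pos, markers$chrom)
      for (k in seq_along(r$gaps$threshold)) {
        expect_equal(r$gaps$n_gaps[k],
                     brute_gap_count(split_pos, r$gaps$threshold[k]))
      }
      # anti-monotone in threshold
      expect_true(all(diff(r$gaps$n_gaps) <= 0))
    }
  })
})

test_that("genetic gap inventory works on cM coordinates", {
  m <- tibble::tibble(chrom = "Chr01", pos_cM = c(0, 25))
  r <- genetic_density_and_gaps(m, c(Chr01 = 100))
  expect_equal(r$gaps$n_gaps, c(1L, 1L))
  even <- tibble::tibble(chrom = "Chr01", pos_cM = seq(0, 100, by = 5))
  r2 <- genetic_density_and_gaps(even, c(Chr01 = 100))
  expect_equal(r2$gaps$n_gaps, c(0L, 0L))
  expect_equal(glance(r2)$density, 21 / 100)
})

test_that("nearest-anchor placement agrees with exhaustive search", {
  map <- tibble::tibble(marker_id = c("a1", "a2"), chrom = "Chr01",
                        pos_bp = c(1000, 2000), pos_cM = c(0, 5))
  q <- tibble::tibble(chrom = "Chr01", pos = c(1400, 1600, 1500))
  got <- assign_genetic_positions(q, map)
  expect_equal(got$pos_cM, c(0, 5, 0))  # tie at 1500 goes to the smaller bp

  unplaced <- assign_genetic_positions(tibble::tibble(chrom = "Chr09", pos = 1),
                                       map)
  expect_false(unplaced$placed)
  expect_true(is.na(unplaced$pos_cM))

  withr::with_seed(123, {
    for (i in 1:5) {
      anchors <- tibble::tibble(
        marker_id = sprintf("m%d", 1:30), chrom = "Chr01",
        pos_bp = sort(sample.int(1e6, 30)),
        pos_cM = sort(runif(30, 0, 120)))
      qs <- tibble::tibble(chrom = "Chr01", pos = sample.int(1e6, 100))
      got <- assign_genetic_positions(qs, anchors)
      want <- vapply(qs$pos, brute_nearest_cM,
                     numeric(1), anchors$pos_bp, anchors$pos_cM)
      expect_equal(got$pos_cM, want)
    }
  })
})
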