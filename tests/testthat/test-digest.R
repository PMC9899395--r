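# In-silico digestion: cut-site scanning, methylation suppression, and
# fragment assembly.

test_that("cut coordinates follow the asterisk convention", {
  g <- c(chr1 = "AACTGCAGTTCCGGAA")
  cs <- find_cut_sites(g, c("PstI", "MspI"))
  expect_equal(cs$coordinate, c(7L, 11L))
  expect_equal(cs$enzyme, c("PstI", "MspI"))
  expect_equal(cs$site_start, c(2L, 10L))
})

test_that("overlapping recognition sites each yield a cut", {
  cs <- find_cut_sites(c(chr1 = "GCAGCTGC"), "ApeKI")
  expect_equal(cs$site_start, c(0L, 3L))
  expect_equal(cs$coordinate, c(1L, 4L))
})

test_that("N-containing windows never match", {
  cs <- find_cut_sites(c(chr1 = "AACCNGGTTCCGG"), "MspI")
  expect_equal(cs$site_start, 9L)
})

test_that("full methylation sensitivity blocks methylated sites", {
  g <- c(chr1 = "AACTGCAGTT")
  meth <- tibble::tibble(chrom = "chr1", pos = 5L)  # site-internal C
  expect_equal(nrow(find_cut_sites(g, "PstI", methylation = meth)), 0L)
  # methylation-insensitive enzymes are unaffected
  g2 <- c(chr1 = "AACCGGTT")
  meth2 <- tibble::tibble(chrom = "chr1", pos = 3L)
  expect_equal(nrow(find_cut_sites(g2, "MspI", methylation = meth2)), 1L)
  # the bottom-strand cytosine (G position) also blocks
  meth3 <- tibble::tibble(chrom = "chr1", pos = 7L)  # the last G of CTGCAG
  expect_equal(nrow(find_cut_sites(g, "PstI", methylation = meth3)), 0L)
})

test_that("partial sensitivity suppresses methylated sites stochastically and reproducibly", {
  g <- make_genome(c(Chr01 = 50000), gc = 0.5, seed = 11)
  meth <- make_methylation(g, cpg_fraction = 1, seed = 12)
  raw <- find_cut_sites(g, "ApeKI")
  b1 <- find_cut_sites(g, "ApeKI", methylation = meth, partial_block_prob = 0.5, seed = 5)
  b2 <- find_cut_sites(g, "ApeKI", methylation = meth, partial_block_prob = 0.5, seed = 5)
  expect_identical(b1, b2)
  expect_lt(nrow(b1), nrow(raw))
  none <- find_cut_sites(g, "ApeKI", methylation = meth, partial_block_prob = 0, seed = 5)
  all_blocked <- find_cut_sites(g, "ApeKI", methylation = meth,
                                partial_block_prob = 1, seed = 5)
  expect_equal(nrow(none), nrow(raw))
  # with every CpG methylated and certain blocking, only CpG-free sites remain
  expect_lt(nrow(all_blocked), nrow(b1))
})

test_that("non-palindromic sites are rejected", {
  enz <- tibble::tibble(name = "FakeI", site = "GACGT", cut_offset = 1,
                        methylation_sensitivity = "none")
  expect_error(find_cut_sites(c(chr1 = "AAAA"), enz),
               class = "gbs_unsupported_enzyme")
})

test_that("digestion matches a naive IUPAC-expansion scanner on random genomes", {
  reg <- gbs_enzymes()
  for (seed in c(101, 202, 303)) {
    s <- random_genome_string(50000, seed)
    g <- c(chrA = s)
    for (i in seq_len(nrow(reg))) {
      cs <- find_cut_sites(g, reg$name[i])
      expected <- naive_site_starts(s, reg$site[i])
      expect_equal(cs$site_start, expected,
                   info = paste(reg$name[i], "seed", seed))
      expect_equal(cs$coordinate, expected + reg$cut_offset[i])
    }
  }
})

test_that("fragments tile each sequence exactly", {
  g <- make_genome(c(A = 30000, B = 20000), gc = 0.45, seed = 7)
  cs <- find_cut_sites(g, c("PstI", "NsiI", "MspI"))
  fr <- digest(g, cs)
  for (ch in names(g)) {
    f <- fr[fr$chrom == ch, ]
    expect_equal(sum(f$width), Biostrings::width(g)[match(ch, names(g))])
    expect_equal(f$start[-1], f$end[-nrow(f)])
    expect_equal(f$start[1], 0)
    n_cuts <- length(unique(cs$coordinate[cs$chrom == ch]))
    expect_equal(nrow(f), n_cuts + 1)
    # interior boundary labels agree on both sides
    expect_equal(f$right[-nrow(f)], f$left[-1])
  }
  expect_equal(fr$left[1], "TERMINUS")
  expect_equal(fr$right[nrow(fr)], "TERMINUS")
})

test_that("zero cut sites give one terminal fragment", {
  g <- c(chr1 = strrep("A", 100))
  fr <- digest(g, find_cut_sites(g, "MspI"))
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$width, 100L)
  expect_equal(c(fr$left, fr$right), c("TERMINUS", "TERMINUS"))
})

test_that("digesting the reverse complement mirrors the fragment structure", {
  # palindromic sites match at mirrored positions, so interior fragments
  # (between two cuts) keep their lengths; the two terminal fragments shift
  # by |site length - 2 * cut offset| when the cut is off-center
  g <- make_genome(c(Chr01 = 40000), gc = 0.5, seed = 21)
  rc <- Biostrings::reverseComplement(g)
  names(rc) <- names(g)
  reg <- gbs_enzymes()
  for (enz in c("PstI", "MspI", "ApeKI")) {
    f1 <- digest_genome(g, enz)
    f2 <- digest_genome(rc, enz)
    expect_equal(nrow(f1), nrow(f2), info = enz)
    expect_equal(sum(f1$width), sum(f2$width), info = enz)
    interior <- function(f) sort(f$width[f$left != "TERMINUS" & f$right != "TERMINUS"])
    expect_equal(interior(f1), interior(f2), info = enz)
    d <- nchar(reg$site[reg$name == enz]) - 2 * reg$cut_offset[reg$name == enz]
    first1 <- f1$width[1]; last1 <- f1$width[nrow(f1)]
    expect_equal(f2$width[1], last1 - d, info = enz)
    expect_equal(f2$width[nrow(f2)], first1 + d, info = enz)
  }
})

test_that("mean fragment length approaches the expected spacing", {
  g <- make_genome(c(Chr01 = 2e6), gc = 0.5, seed = 31)
  fr <- digest_genome(g, "MspI")
  expect_lt(abs(mean(fr$width) - 256) / 256, 0.05)
})

test_that("coincident cuts are resolved by registry order with a warning", {
  # two names for the same site: every cut coordinate coincides
  enz <- tibble::tibble(
    name = c("MspA", "MspB"),
    site = c("CCGG", "CCGG"),
    cut_offset = c(1L, 1L),
    methylation_sensitivity = "none"
  )
  g <- c(chr1 = "AACCGGTT")
  cs <- find_cut_sites(g, enz)
  expect_equal(nrow(cs), 2L)
  expect_warning(fr <- digest(g, cs), "coincident")
  expect_equal(nrow(fr), 2L)
  expect_equal(fr$right[1], "MspA")
})

test_that("unsorted or out-of-bounds cut sites are rejected", {
  g <- c(chr1 = "AACCGGTTCCGGAA")
  cs <- find_cut_sites(g, "MspI")
  expect_error(digest(g, cs[c(2, 1), ]), class = "gbs_bad_argument")
  bad <- cs
  bad$coordinate[1] <- 99L
  expect_error(digest(g, bad), class = "gbs_bad_argument")
})

test_that("evaluate_combinations is consistent and monotone in enzymes", {
  g <- make_genome(c(Chr01 = 100000), gc = 0.5, seed = 41)
  res <- evaluate_combinations(g, list("PstI", "MspI", c("PstI", "MspI")))
  total <- function(comb) {
    res$n_cut_sites[res$combination == comb & res$chrom == "(genome)" &
                      res$enzyme == "(combined)"]
  }
  n_pst <- total("PstI")
  n_msp <- total("MspI")
  n_both <- total("PstI+MspI")
  expect_gte(n_both, n_pst)
  expect_gte(n_both, n_msp)
  # single-enzyme combination equals a direct scan
  expect_equal(n_pst, nrow(find_cut_sites(g, "PstI")))
  # union property: no methylation, so counts add up to coincidences
  cs_p <- find_cut_sites(g, "PstI")
  cs_m <- find_cut_sites(g, "MspI")
  coincident <- length(intersect(cs_p$coordinate, cs_m$coordinate))
  expect_equal(n_both, n_pst + n_msp)
  fr_both <- res[res$combination == "PstI+MspI" & res$chrom == "(genome)" &
                   res$enzyme == "(combined)", ]
  expect_equal(fr_both$n_fragments,
               n_pst + n_msp - coincident + 1L)
  expect_error(evaluate_combinations(g, list()), class = "gbs_bad_argument")
})
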