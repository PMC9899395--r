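# Independent oracles used across tests. These deliberately avoid the
# package's own scanning/statistics code paths.

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# expand an IUPAC site into all concrete ACGT words
expand_words <- function(site) {
  chars <- strsplit(site, "")[[1]]
  words <- ""
  for (ch in chars) {
    words <- as.vector(outer(words, iupac_sets[[ch]], paste0))
  }
  words
}

# naive overlapping substring scan via perl lookahead; returns 0-based
# match starts of any expansion of `site` in `seq`
naive_site_starts <- function(seq, site) {
  starts <- integer(0)
  for (w in expand_words(site)) {
    m <- gregexpr(paste0("(?=", w, ")"), seq, perl = TRUE)[[1]]
    if (m[1] != -1) starts <- c(starts, as.integer(m) - 1L)
  }
  sort(unique(starts))
}

# brute-force gap count: all consecutive-marker distances > threshold
brute_gap_count <- function(pos_by_chrom, threshold) {
  sum(vapply(pos_by_chrom, function(p) {
    p <- sort(p)
    if (length(p) < 2) return(0L)
    sum(diff(p) > threshold)
  }, integer(1)))
}

# exhaustive nearest-anchor search with smaller-bp tie-break
brute_nearest_cM <- function(q, anchors_bp, anchors_cM) {
  d <- abs(anchors_bp - q)
  anchors_cM[which.min(d)]  # which.min takes the first (smallest bp) minimum
}

# brute-force IBS distance between two genotype vectors ("a/b" strings)
brute_ibs <- function(ga, gb) {
  ok <- !is.na(ga) & !is.na(gb)
  if (!any(ok)) return(NA_real_)
  shared <- mapply(function(x, y) {
    ax <- strsplit(x, "/")[[1]]
    ay <- strsplit(y, "/")[[1]]
    s <- 0
    for (a in ax) {
      hit <- match(a, ay)
      if (!is.na(hit)) {
        s <- s + 1
        ay <- ay[-hit]
      }
    }
    s
  }, ga[ok], gb[ok])
  1 - mean(shared) / 2
}

random_genome_string <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}
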