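# Synthetic data generators: random genomes with controlled base
# composition, CpG methylation tracks, consensus genetic maps, toy VCFs
# with constructive filter truth, and FASTQ. Every generator is a pure
# function of its parameters and seed.

#' Generate a random genome
#'
#' Draws i.i.d. bases at a stated GC fraction. `gc` may be a single value
#' (uniform composition) or a length-2 vector giving the GC fraction at the
#' start and end of every sequence, interpolated linearly across windows of
#' `gc_window` bp to emulate the compositional gradients of real
#' chromosomes.
#'
#' @param lengths Integer vector of sequence lengths; names become sequence
#'   ids (defaults `Chr01`, `Chr02`, ...).
#' @param gc GC fraction in `[0, 1]`, scalar or `c(start, end)` gradient.
#' @param gc_window Window size in bp for the gradient (ignored for scalar
#'   `gc`).
#' @param seed Optional integer seed; identical seeds give identical
#'   genomes.
#' @return A named `DNAStringSet`.
#' @examples
#' make_genome(c(Chr01 = 10000), gc = 0.35, seed = 1)
#' @export
make_genome <- function(lengths, gc = 0.5, gc_window = 10000, seed = NULL) {
  if (any(lengths <= 0)) abort("Sequence lengths must be positive.",
                               class = "gbs_bad_argument")
  if (any(gc < 0 | gc > 1) || !length(gc) %in% c(1L, 2L)) {
    abort("`gc` must be a fraction in [0, 1], scalar or length 2.",
          class = "gbs_bad_argument")
  }
  nm <- names(lengths) %||% sprintf("Chr%02d", seq_along(lengths))
  seqs <- with_seed_if(seed, {
    lapply(lengths, function(L) {
      L <- as.integer(L)
      gc_at <- if (length(gc) == 1L) {
        rep(gc, L)
      } else {
        win <- pmin((seq_len(L) - 1L) %/% gc_window * gc_window, L - 1L)
        gc[1] + (gc[2] - gc[1]) * win / max(L - 1L, 1L)
      }
      is_gc <- runif(L) < gc_at
      strong <- sample(c("G", "C"), L, replace = TRUE)
      weak <- sample(c("A", "T"), L, replace = TRUE)
      paste(ifelse(is_gc, strong, weak), collapse = "")
    })
  })
  Biostrings::DNAStringSet(setNames(unlist(seqs), nm))
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet` (or coercible input).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' Generate a CpG methylation track
#'
#' Marks each cytosine of each CpG dinucleotide (the top-strand C and the
#' bottom-strand C, encoded at the paired G position) methylated
#' independently with probability `cpg_fraction`.
#'
#' @inheritParams find_cut_sites
#' @param cpg_fraction Per-cytosine methylation probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `chrom`, `pos` (0-based), `strand`.
#' @export
make_methylation <- function(genome, cpg_fraction, seed = NULL) {
  if (cpg_fraction < 0 || cpg_fraction > 1) {
    abort("`cpg_fraction` must be in [0, 1].", class = "gbs_bad_argument")
  }
  genome <- as_genome(genome)
  sites <- purrr::map(names(genome), function(chrom) {
    m <- Biostrings::matchPattern("CG", genome[[chrom]])
    if (length(m) == 0) return(NULL)
    starts0 <- Biostrings::start(m) - 1L
    tibble::tibble(
      chrom = chrom,
      pos = c(starts0, starts0 + 1L),
      strand = rep(c("+", "-"), each = length(starts0))
    )
  })
  cpg <- dplyr::bind_rows(sites)
  if (nrow(cpg) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(), strand = character()))
  }
  cpg <- cpg |> dplyr::arrange(match(.data$chrom, names(genome)), .data$pos)
  keep <- with_seed_if(seed, runif(nrow(cpg)) < cpg_fraction)
  cpg[keep, ]
}

#' Write a methylation track as BED
#'
#' Three-column BED (chrom, pos, pos + 1), 0-based half-open.
#'
#' @param track A methylation tibble from [make_methylation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation_bed <- function(track, path) {
  readr::write_tsv(
    tibble::tibble(chrom = track$chrom, start = track$pos, end = track$pos + 1L),
    path, col_names = FALSE)
  invisible(path)
}

#' Read a methylation BED track
#'
#' @param path Path to a 3-column BED file (chrom, start, end), 0-based.
#' @return A tibble with columns `chrom`, `pos`.
#' @export
read_methylation_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                       col_types = "cii")
  tibble::tibble(chrom = x$chrom, pos = x$start)
}

#' Generate a consensus genetic map
#'
#' Places `anchors_per_chrom` anchors evenly along each chromosome and
#' assigns centimorgan positions at a linear `cM_per_Mb` rate with bounded
#' jitter. Jitter is truncated to less than half the inter-anchor cM gap,
#' so the map is monotone non-decreasing by construction, as consensus maps
#' are.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param anchors_per_chrom Number of anchors per chromosome (>= 2).
#' @param cM_per_Mb Linear recombination rate (default 2.5 cM/Mb, a typical
#'   genome-wide average for a compact plant genome).
#' @param jitter_cM Maximum absolute jitter; internally capped below half
#'   the anchor spacing.
#' @param seed Optional integer seed.
#' @return A tibble with columns `marker_id`, `chrom`, `pos_bp`, `pos_cM`.
#' @export
make_consensus_map <- function(chrom_lengths, anchors_per_chrom = 50,
                               cM_per_Mb = 2.5, jitter_cM = 0.5, seed = NULL) {
  check_positive_scalar(cM_per_Mb, "cM_per_Mb")
  if (anchors_per_chrom < 2) {
    abort("`anchors_per_chrom` must be at least 2.", class = "gbs_bad_argument")
  }
  nm <- names(chrom_lengths) %||% sprintf("Chr%02d", seq_along(chrom_lengths))
  with_seed_if(seed, {
    maps <- purrr::map2(nm, as.numeric(chrom_lengths), function(chrom, L) {
      pos_bp <- round(seq(1, L, length.out = anchors_per_chrom))
      base_cM <- cM_per_Mb * (pos_bp - 1) / 1e6
      gap <- min(diff(base_cM))
      cap <- min(jitter_cM, 0.49 * gap)
      jit <- runif(anchors_per_chrom, -cap, cap)
      jit[1] <- 0  # anchor the map origin at 0 cM
      tibble::tibble(
        marker_id = sprintf("%s_anchor_%03d", chrom, seq_len(anchors_per_chrom)),
        chrom = chrom,
        pos_bp = as.integer(pos_bp),
        pos_cM = base_cM + jit
      )
    })
    dplyr::bind_rows(maps)
  })
}

#' Generate a synthetic VCF with constructive filter truth
#'
#' Simulates diploid genotype records realizing stated distributions of
#' QUAL, mapping quality, per-site missingness, heterozygosity and minor
#' allele frequency, with controlled fractions of indels, multiallelic
#' sites and scaffold-placed variants. Alongside the records it returns a
#' truth table flagging, for each record, whether it passes the standard
#' hard filters and the first failing rule - computed from the generated
#' attributes at generation time, so filter implementations can be tested
#' against an exact constructive oracle.
#'
#' @param n_samples Number of diploid samples.
#' @param n_sites Number of variant records.
#' @param chrom_lengths Named vector of sequence lengths; names matching
#'   `scaffold_pattern` count as unassembled scaffolds.
#' @param qual Function `(n) -> numeric` drawing QUAL values, or a single
#'   number.
#' @param mq As `qual`, for the INFO MQ field; `NA` values are emitted as a
#'   missing MQ key.
#' @param missing_rate Function `(n) -> numeric` drawing per-site missing
#'   rates in `[0, 1]`, or a single number.
#' @param het_rate Per-call heterozygosity probability.
#' @param maf Function `(n) -> numeric` drawing per-site alternate allele
#'   frequencies, or a single number.
#' @param frac_indel,frac_multiallelic Fractions of records made indels /
#'   triallelic.
#' @param scaffold_pattern Regex identifying scaffold sequence names.
#' @param config Filter thresholds used for the truth flags (a
#'   [filter_config()]).
#' @param seed Optional integer seed.
#' @return A list with elements `records` (a variant tibble as returned by
#'   [read_variants()]) and `truth` (tibble: `site`, `pass`, `reason`).
#' @export
make_vcf <- function(n_samples = 16, n_sites = 1000,
                     chrom_lengths = c(Chr01 = 5e7, Chr02 = 5e7, scaffold_1 = 1e6),
                     qual = function(n) stats::rexp(n, 1 / 40),
                     mq = function(n) stats::rnorm(n, 45, 10),
                     missing_rate = function(n) runif(n, 0, 1),
                     het_rate = 0.05,
                     maf = function(n) runif(n, 0.02, 0.5),
                     frac_indel = 0.1, frac_multiallelic = 0.05,
                     scaffold_pattern = "^scaffold",
                     config = filter_config(),
                     seed = NULL) {
  as_draw <- function(x) if (is.function(x)) x else function(n) rep(x, n)
  qual_f <- as_draw(qual); mq_f <- as_draw(mq)
  miss_f <- as_draw(missing_rate); maf_f <- as_draw(maf)
  nm <- names(chrom_lengths)
  if (is.null(nm)) abort("`chrom_lengths` must be named.", class = "gbs_bad_argument")
  samples <- sprintf("S%02d", seq_len(n_samples))
  bases <- c("A", "C", "G", "T")

  with_seed_if(seed, {
    chrom <- sample(nm, n_sites, replace = TRUE,
                    prob = as.numeric(chrom_lengths) / sum(chrom_lengths))
    pos <- vapply(chrom, function(ch) {
      sample.int(as.integer(chrom_lengths[[ch]]), 1)
    }, integer(1))
    # unique positions per chromosome
    while (anyDuplicated(paste(chrom, pos))) {
      d <- duplicated(paste(chrom, pos))
      pos[d] <- vapply(chrom[d], function(ch) {
        sample.int(as.integer(chrom_lengths[[ch]]), 1)
      }, integer(1))
    }
    type <- sample(c("snp", "indel", "multi"), n_sites, replace = TRUE,
                   prob = c(1 - frac_indel - frac_multiallelic,
                            frac_indel, frac_multiallelic))
    ref <- sample(bases, n_sites, replace = TRUE)
    alt <- vapply(seq_len(n_sites), function(i) {
      others <- setdiff(bases, ref[i])
      switch(type[i],
             snp = sample(others, 1),
             indel = paste0(ref[i], sample(bases, 1)),
             multi = paste(sample(others, 2), collapse = ","))
    }, character(1))
    quals <- round(qual_f(n_sites), 1)
    mqs <- round(mq_f(n_sites), 1)
    p_alt <- maf_f(n_sites)
    m_rate <- miss_f(n_sites)

    gt <- matrix(NA_character_, n_sites, n_samples,
                 dimnames = list(NULL, samples))
    for (i in seq_len(n_sites)) {
      miss <- runif(n_samples) < m_rate[i]
      het <- runif(n_samples) < het_rate
      # allele frequency target p_alt: hom-alt probability adjusted for hets
      p_hom_alt <- max(0, min(1, (p_alt[i] - het_rate / 2) / max(1 - het_rate, 1e-9)))
      hom_alt <- runif(n_samples) < p_hom_alt
      g <- ifelse(het, "0/1", ifelse(hom_alt, "1/1", "0/0"))
      g[miss] <- NA_character_
      gt[i, ] <- g
    }

    records <- tibble::tibble(
      chrom = chrom, pos = as.integer(pos),
      id = sprintf("site%04d", seq_len(n_sites)),
      ref = ref, alt = alt, qual = quals, mq = mqs
    )
    records$gt <- gt

    truth <- constructive_truth(records, config, scaffold_pattern, nm)
    list(records = records, truth = truth, samples = samples)
  })
}

# Truth flags computed from generated attributes, mirroring the stated
# filter semantics; kept separate from filter_variants() so tests compare
# two code paths.
constructive_truth <- function(records, config, scaffold_pattern, chrom_names) {
  n <- nrow(records)
  gt <- records$gt
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    g <- gt[i, ]
    n_missing <- sum(is.na(g))
    non_missing <- g[!is.na(g)]
    alleles <- strsplit(records$alt[i], ",", fixed = TRUE)[[1]]
    is_indel <- nchar(records$ref[i]) != 1 || any(nchar(alleles) != 1)
    het <- vapply(non_missing, function(x) {
      ab <- strsplit(x, "[/|]")[[1]]
      ab[1] != ab[2]
    }, logical(1))
    qual_fail <- records$qual[i] < config$min_qual
    mq_fail <- is.na(records$mq[i]) || records$mq[i] < config$min_mq
    low_quality <- if (config$qual_mq_rule == "either") qual_fail || mq_fail else qual_fail && mq_fail
    r <- if (config$qual_mq_rule == "either" && qual_fail) "low_qual"
      else if (config$qual_mq_rule == "either" && mq_fail) "low_mq"
      else if (config$qual_mq_rule == "both" && low_quality) "low_qual"
      else if (grepl(scaffold_pattern, records$chrom[i])) "scaffold"
      else if (config$drop_indels && is_indel) "indel"
      else if (config$biallelic_only && length(alleles) != 1) "multiallelic"
      else if (n_missing / length(g) >= config$max_missing_rate) "missing"
      else if (length(het) > 0 && mean(het) >= config$max_het_rate) "het"
      else NA_character_
    reason[i] <- r
  }
  tibble::tibble(site = records$id, pass = is.na(reason), reason = reason)
}

#' Write variant records as VCF
#'
#' Serializes a variant tibble (as produced by [make_vcf()] or
#' [read_variants()]) as a minimal valid VCF 4.2 file with QUAL, INFO/MQ
#' and per-sample GT fields.
#'
#' @param records A variant tibble with columns `chrom`, `pos`, `id`,
#'   `ref`, `alt`, `qual`, `mq` and genotype matrix column `gt`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path) {
  samples <- colnames(records$gt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt <- records$gt
  gt[is.na(gt)] <- "./."
  body <- vapply(seq_len(nrow(records)), function(i) {
    info <- if (is.na(records$mq[i])) "." else sprintf("MQ=%g", records$mq[i])
    paste(c(records$chrom[i], records$pos[i], records$id[i], records$ref[i],
            records$alt[i], format(records$qual[i]), ".", info, "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate a synthetic FASTQ file
#'
#' Writes `n` fixed-length records with constant quality, for exercising
#' subsampling. Record ids are `read000001`, ... so inclusion can be traced.
#'
#' @param n Number of records.
#' @param read_length Read length in bp.
#' @param path Output path.
#' @param seed Optional integer seed.
#' @return `path`, invisibly.
#' @export
make_fastq <- function(n, read_length = 100, path, seed = NULL) {
  with_seed_if(seed, {
    lines <- character(4 * n)
    for (i in seq_len(n)) {
      seqs <- paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
                    collapse = "")
      lines[(i - 1) * 4 + 1:4] <- c(sprintf("@read%06d", i), seqs, "+",
                                    strrep("I", read_length))
    }
    writeLines(lines, path)
  })
  invisible(path)
}
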