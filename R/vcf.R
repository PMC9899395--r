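# VCF boundary and hard filtering. Reading goes through vcfR; in-memory
# records are a tidy tibble (one row per site) with a genotype matrix
# column, VCF's 1-based positions preserved.

#' Read a VCF into a variant tibble
#'
#' Parses a VCF 4.x file (plain or gzipped) into the tidy record format
#' used by the filtering and diagnostic functions: one row per site with
#' `chrom`, `pos` (1-based), `id`, `ref`, `alt`, `qual`, `mq` (from
#' INFO/MQ, `NA` when absent) and a genotype matrix column `gt` with
#' entries like `"0/1"` and `NA` for missing calls.
#'
#' @param path Path to a VCF file.
#' @return A variant tibble.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[gt %in% c("./.", ".|.", ".")] <- NA_character_
  rownames(gt) <- NULL
  out <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = fix$ID,
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    mq = mq
  )
  out$gt <- gt
  out
}

#' Hard-filter configuration for variant records
#'
#' The standard GBS post-calling filter set: drop low-quality sites
#' (`QUAL < min_qual` or `MQ < min_mq`), sites on unassembled scaffolds,
#' indels and non-biallelic sites, then retain only sites with missing-data
#' rate strictly below `max_missing_rate` and site heterozygosity strictly
#' below `max_het_rate`.
#'
#' @param min_qual Minimum QUAL (default 10).
#' @param min_mq Minimum INFO/MQ (default 30); a missing MQ fails.
#' @param max_missing_rate Exclusive upper bound on the fraction of missing
#'   genotype calls (default 0.8).
#' @param max_het_rate Exclusive upper bound on the heterozygous fraction
#'   among non-missing calls (default 0.1).
#' @param scaffold_pattern Regex matching sequence names to exclude
#'   (default `"^scaffold"`); `NULL` disables.
#' @param allowed_chromosomes Optional explicit whitelist of sequence
#'   names; when given, `scaffold_pattern` is ignored.
#' @param biallelic_only Keep only single-ALT sites (default TRUE).
#' @param drop_indels Drop sites with any allele longer than 1 bp (default
#'   TRUE).
#' @param qual_mq_rule `"either"` (default): remove when either QUAL or MQ
#'   fails; `"both"`: remove only when both fail.
#' @return A `gbs_filter_config` list.
#' @export
filter_config <- function(min_qual = 10, min_mq = 30, max_missing_rate = 0.8,
                          max_het_rate = 0.1, scaffold_pattern = "^scaffold",
                          allowed_chromosomes = NULL, biallelic_only = TRUE,
                          drop_indels = TRUE, qual_mq_rule = c("either", "both")) {
  qual_mq_rule <- match.arg(qual_mq_rule)
  if (max_missing_rate < 0 || max_missing_rate > 1 ||
      max_het_rate < 0 || max_het_rate > 1) {
    abort("Rate thresholds must lie in [0, 1].", class = "gbs_bad_argument")
  }
  structure(
    list(min_qual = min_qual, min_mq = min_mq,
         max_missing_rate = max_missing_rate, max_het_rate = max_het_rate,
         scaffold_pattern = scaffold_pattern,
         allowed_chromosomes = allowed_chromosomes,
         biallelic_only = biallelic_only, drop_indels = drop_indels,
         qual_mq_rule = qual_mq_rule),
    class = "gbs_filter_config"
  )
}

site_het_rate <- function(g) {
  non_missing <- g[!is.na(g)]
  if (length(non_missing) == 0) return(NA_real_)
  ab <- strsplit(non_missing, "[/|]")
  mean(vapply(ab, function(x) x[1] != x[2], logical(1)))
}

#' Filter variant records
#'
#' Applies the hard filters of [filter_config()] and annotates every record
#' with a pass flag and the first failing rule, in the fixed order:
#' `low_qual`, `low_mq`, `scaffold`, `indel`, `multiallelic`, `missing`,
#' `het`. Use `dplyr::filter(out, pass)` for the retained set.
#'
#' @param records A variant tibble from [read_variants()] or [make_vcf()].
#' @param config A [filter_config()].
#' @return The input tibble with added logical `pass` and character
#'   `reason` (`NA` for retained records) columns.
#' @export
filter_variants <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "gbs_filter_config"))
  n <- nrow(records)
  gt <- records$gt

  qual_fail <- is.na(records$qual) | records$qual < config$min_qual
  mq_fail <- is.na(records$mq) | records$mq < config$min_mq
  if (!is.null(config$allowed_chromosomes)) {
    chrom_fail <- !(records$chrom %in% config$allowed_chromosomes)
  } else if (!is.null(config$scaffold_pattern)) {
    chrom_fail <- grepl(config$scaffold_pattern, records$chrom)
  } else {
    chrom_fail <- rep(FALSE, n)
  }
  alt_alleles <- strsplit(records$alt, ",", fixed = TRUE)
  indel <- nchar(records$ref) != 1 |
    vapply(alt_alleles, function(a) any(nchar(a) != 1), logical(1))
  multi <- lengths(alt_alleles) != 1
  missing_rate <- rowMeans(is.na(gt))
  het_rate <- vapply(seq_len(n), function(i) site_het_rate(gt[i, ]), numeric(1))

  reason <- rep(NA_character_, n)
  if (config$qual_mq_rule == "either") {
    reason[is.na(reason) & qual_fail] <- "low_qual"
    reason[is.na(reason) & mq_fail] <- "low_mq"
  } else {
    reason[is.na(reason) & qual_fail & mq_fail] <- "low_qual"
  }
  reason[is.na(reason) & chrom_fail] <- "scaffold"
  if (config$drop_indels) reason[is.na(reason) & indel] <- "indel"
  if (config$biallelic_only) reason[is.na(reason) & multi] <- "multiallelic"
  reason[is.na(reason) & missing_rate >= config$max_missing_rate] <- "missing"
  reason[is.na(reason) & !is.na(het_rate) & het_rate >= config$max_het_rate] <- "het"

  records$pass <- is.na(reason)
  records$reason <- reason
  records
}
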