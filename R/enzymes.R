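# Restriction-enzyme model: IUPAC recognition sites, cut offsets,
# methylation-sensitivity classes, and the closed-form site arithmetic
# (GC content, match probability, expected spacing) used to choose
# enzymes for a reduced-representation design.

# IUPAC ambiguity codes and the concrete bases each expands to.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

site_chars <- function(site) {
  chars <- strsplit(toupper(site), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_CODES))
  if (length(bad) > 0) {
    abort(sprintf("Invalid IUPAC character(s) in site '%s': %s",
                  site, paste(unique(bad), collapse = ", ")),
          class = "gbs_invalid_site")
  }
  if (length(chars) == 0) {
    abort("Recognition site must be non-empty.", class = "gbs_invalid_site")
  }
  chars
}

#' Built-in restriction enzyme registry
#'
#' Returns the packaged registry of restriction enzymes used throughout the
#' toolkit: the three-enzyme design set (PstI, NsiI, MspI), the classic
#' single-enzyme GBS cutter ApeKI, and six further enzymes spanning
#' recognition sites of 33/66% GC content (BglII, BclI, BlnI, BamHI, BfaI,
#' BstUI) for combination screening. The `*` position of the conventional
#' cut-mark notation (e.g. `CTGCA*G`) is stored as `cut_offset`, the number
#' of site bases left of the top-strand cleavage point.
#'
#' `methylation_sensitivity` is a three-level class (`"none"`, `"partial"`,
#' `"full"`) describing blocking by cytosine methylation within the
#' recognition site; its quantitative effect is a parameter of digestion,
#' not of the enzyme.
#'
#' @return A tibble with columns `name`, `site`, `cut_offset`,
#'   `methylation_sensitivity`.
#' @examples
#' gbs_enzymes()
#' @export
gbs_enzymes <- function() {
  reg <- tibble::tribble(
    ~name,    ~site,     ~cut_offset, ~methylation_sensitivity,
    "ApeKI",  "GCWGC",   1L,          "partial",
    "PstI",   "CTGCAG",  5L,          "full",
    "NsiI",   "ATGCAT",  5L,          "none",
    "MspI",   "CCGG",    1L,          "none",
    "BglII",  "AGATCT",  1L,          "none",
    "BclI",   "TGATCA",  1L,          "none",
    "BlnI",   "CCTAGG",  1L,          "none",
    "BamHI",  "GGATCC",  1L,          "none",
    "BfaI",   "CTAG",    1L,          "none",
    "BstUI",  "CGCG",    2L,          "full"
  )
  validate_enzyme_tbl(reg)
}

validate_enzyme_tbl <- function(x) {
  required <- c("name", "site", "cut_offset", "methylation_sensitivity")
  if (!all(required %in% names(x))) {
    abort(sprintf("Enzyme table must have columns: %s.",
                  paste(required, collapse = ", ")),
          class = "gbs_bad_enzyme")
  }
  x <- tibble::as_tibble(x)
  x$site <- toupper(x$site)
  x$cut_offset <- as.integer(x$cut_offset)
  if (any(duplicated(x$name))) {
    abort("Enzyme names must be unique.", class = "gbs_bad_enzyme")
  }
  for (i in seq_len(nrow(x))) {
    chars <- site_chars(x$site[i])
    if (length(chars) < 3) {
      abort(sprintf("Enzyme %s: recognition site must be at least 3 bp.", x$name[i]),
            class = "gbs_bad_enzyme")
    }
    if (is.na(x$cut_offset[i]) || x$cut_offset[i] < 0 || x$cut_offset[i] > length(chars)) {
      abort(sprintf("Enzyme %s: cut_offset must lie in [0, site length].", x$name[i]),
            class = "gbs_bad_enzyme")
    }
  }
  if (!all(x$methylation_sensitivity %in% c("none", "partial", "full"))) {
    abort("methylation_sensitivity must be one of 'none', 'partial', 'full'.",
          class = "gbs_bad_enzyme")
  }
  x[, required]
}

#' Read an enzyme registry file
#'
#' Reads a TSV with columns `name`, `site`, `cut_offset`,
#' `methylation_sensitivity` (the same format as the packaged registry at
#' `system.file("extdata", "enzymes.tsv", package = "gbs3d")`), validates it,
#' and returns it as a tibble.
#'
#' @param path Path to a tab-separated enzyme definition file.
#' @return A validated enzyme tibble.
#' @export
read_enzymes <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    site = readr::col_character(),
    cut_offset = readr::col_integer(),
    methylation_sensitivity = readr::col_character()
  ))
  validate_enzyme_tbl(x)
}

# Resolve a user-supplied enzyme selection (character names looked up in the
# built-in registry, or a full enzyme table) to a validated tibble whose row
# order defines registry precedence for tie-breaking.
resolve_enzymes <- function(enzymes) {
  if (is.character(enzymes)) {
    reg <- gbs_enzymes()
    missing <- setdiff(enzymes, reg$name)
    if (length(missing) > 0) {
      abort(sprintf("Unknown enzyme(s): %s. Supply a definition table for non built-ins.",
                    paste(missing, collapse = ", ")),
            class = "gbs_unknown_enzyme")
    }
    reg[match(enzymes, reg$name), ]
  } else if (is.data.frame(enzymes)) {
    validate_enzyme_tbl(enzymes)
  } else {
    abort("`enzymes` must be a character vector of registry names or an enzyme table.",
          class = "gbs_bad_enzyme")
  }
}

#' GC content of a recognition site
#'
#' Averages, over the positions of an IUPAC recognition site, the
#' probability that the position is G or C when the ambiguity code is
#' expanded uniformly (so `W` contributes 0, `S` contributes 1, `N`
#' contributes 0.5). `gc_content()` truncates to an integer percentage,
#' matching the usual "66% GC" labelling of enzymes; `gc_fraction()` returns
#' the exact value in `[0, 1]`.
#'
#' @param site Character vector of IUPAC recognition sites (e.g. `"CTGCAG"`).
#' @return `gc_content()`: integer percentages; `gc_fraction()`: numeric
#'   fractions.
#' @examples
#' gc_content(c("GCWGC", "CTGCAG", "ATGCAT", "CCGG"))
#' @export
gc_content <- function(site) {
  as.integer(floor(100 * gc_fraction(site)))
}

#' @rdname gc_content
#' @export
gc_fraction <- function(site) {
  vapply(site, function(s) {
    chars <- site_chars(s)
    mean(vapply(chars, function(ch) {
      exp <- IUPAC_CODES[[ch]]
      mean(exp %in% c("G", "C"))
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-position match probability of a recognition site
#'
#' The probability that an IUPAC site matches at a given position of an
#' i.i.d. uniform ACGT sequence: the number of concrete words the site
#' expands to, divided by `4^L`. For palindromic sites this is the
#' top-strand match probability per position.
#'
#' @inheritParams gc_content
#' @return Numeric vector of probabilities.
#' @examples
#' match_probability("CCGG")    # 1/256
#' match_probability("GCWGC")   # 1/512
#' @export
match_probability <- function(site) {
  vapply(site, function(s) {
    chars <- site_chars(s)
    prod(vapply(chars, function(ch) length(IUPAC_CODES[[ch]]) / 4, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Expected spacing between recognition sites
#'
#' Expected distance in bp between successive top-strand site starts on
#' i.i.d. uniform random DNA: the reciprocal of [match_probability()]. This
#' is the "cuts every ~N bp" figure used to rank enzymes by cutting
#' frequency (4096 bp for a 6-bp cutter, 256 bp for a 4-bp cutter, 512 bp
#' for a 5-bp cutter with one two-fold ambiguity).
#'
#' @inheritParams gc_content
#' @return Numeric vector of expected spacings in bp.
#' @examples
#' expected_spacing(c("CTGCAG", "GCWGC", "CCGG"))
#' @export
expected_spacing <- function(site) {
  p <- match_probability(site)
  if (any(p <= 0)) {
    abort("Site has zero match probability.", class = "gbs_invalid_site")
  }
  1 / p
}

#' Reverse complement of an IUPAC string
#'
#' @inheritParams gc_content
#' @return Character vector of IUPAC reverse complements.
#' @export
iupac_revcomp <- function(site) {
  vapply(site, function(s) {
    chars <- site_chars(s)
    paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Is a recognition site palindromic?
#'
#' TRUE when the IUPAC site equals its own IUPAC reverse complement (with
#' ambiguity-aware complementation, e.g. W<->W, R<->Y). Digestion scans only
#' the top strand and therefore requires palindromic sites.
#'
#' @inheritParams gc_content
#' @return Logical vector.
#' @examples
#' is_palindromic(c("CTGCAG", "GCWGC", "AAAA"))
#' @export
is_palindromic <- function(site) {
  toupper(site) == iupac_revcomp(site)
}
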