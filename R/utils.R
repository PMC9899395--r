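# Shared helpers: seeded evaluation, input normalization, small validators.

# Evaluate `code` under a fixed RNG state when `seed` is given, otherwise use
# the session RNG. Keeps every stochastic entry point reproducible without
# clobbering the caller's random stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Coerce genome input to an uppercase DNAStringSet. Accepts a DNAStringSet,
# a named character vector of sequences, or a path to a FASTA file.
as_genome <- function(x) {
  if (is(x, "DNAStringSet")) {
    gen <- x
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    gen <- Biostrings::readDNAStringSet(x)
    # keep only the first whitespace-delimited token of each FASTA header
    names(gen) <- sub("\\s.*$", "", names(gen))
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    gen <- Biostrings::DNAStringSet(toupper(x))
  } else {
    abort("`genome` must be a DNAStringSet, a named character vector, or a FASTA path.",
          class = "gbs_bad_genome")
  }
  if (any(duplicated(names(gen)))) {
    abort("Genome sequence names must be unique.", class = "gbs_bad_genome")
  }
  if (any(Biostrings::width(gen) == 0L)) {
    abort("Genome sequences must have positive length.", class = "gbs_bad_genome")
  }
  Biostrings::DNAStringSet(toupper(gen))
}

genome_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive scalar.", name), class = "gbs_bad_argument")
  }
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)
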