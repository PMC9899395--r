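# In-silico digestion: scan a genome for recognition-site matches of one or
# more palindromic enzymes, optionally suppress methylated sites, and
# assemble the end-labelled fragment tiling.

#' Locate restriction cut sites in a genome
#'
#' Scans the top strand of every sequence for matches of each enzyme's IUPAC
#' recognition site (palindromy is enforced, so a top-strand scan is
#' complete) and reports the cleavage coordinate of each match. Coordinates
#' are 0-based: a cut at coordinate `c` falls between bases `c - 1` and `c`.
#' Overlapping matches each yield their own cut site; windows containing `N`
#' never match.
#'
#' Methylation handling: with a methylation track, an enzyme with
#' `methylation_sensitivity = "full"` loses every matched site that contains
#' a methylated cytosine (either strand of the duplex window); an enzyme
#' with `"partial"` sensitivity loses such sites independently with
#' probability `partial_block_prob` (seeded); `"none"` is never suppressed.
#' Without a track no suppression occurs.
#'
#' @param genome A `DNAStringSet`, named character vector, or FASTA path.
#' @param enzymes Character vector of built-in enzyme names, or an enzyme
#'   table as returned by [gbs_enzymes()] / [read_enzymes()]. Row/element
#'   order defines precedence when two enzymes cut at the same coordinate.
#' @param methylation Optional methylation track: a data frame with columns
#'   `chrom` and `pos` (0-based position of a methylated cytosine; a
#'   position whose reference base is `G` is interpreted as the
#'   bottom-strand cytosine of the pair).
#' @param partial_block_prob Probability that a methylated site of a
#'   partially sensitive enzyme is suppressed. Default 0.5.
#' @param seed Optional integer seed controlling partial-suppression draws.
#' @return A tibble with columns `chrom`, `coordinate`, `enzyme`,
#'   `site_start`, sorted by sequence then coordinate, with the enzyme
#'   precedence order stored in attribute `"enzyme_order"`.
#' @examples
#' find_cut_sites(c(chr1 = "AACTGCAGTTCCGGAA"), c("PstI", "MspI"))
#' @export
find_cut_sites <- function(genome, enzymes, methylation = NULL,
                           partial_block_prob = 0.5, seed = NULL) {
  genome <- as_genome(genome)
  enz <- resolve_enzymes(enzymes)
  if (!all(is_palindromic(enz$site))) {
    bad <- enz$name[!is_palindromic(enz$site)]
    abort(sprintf("Non-palindromic recognition site(s) not supported: %s.",
                  paste(bad, collapse = ", ")),
          class = "gbs_unsupported_enzyme")
  }
  if (!is.numeric(partial_block_prob) || partial_block_prob < 0 || partial_block_prob > 1) {
    abort("`partial_block_prob` must be a probability.", class = "gbs_bad_argument")
  }
  meth <- normalize_methylation(methylation, genome)

  per_seq <- purrr::map(names(genome), function(chrom) {
    subj <- genome[[chrom]]
    meth_pos <- if (is.null(meth)) integer(0) else meth$pos[meth$chrom == chrom]
    purrr::map(seq_len(nrow(enz)), function(i) {
      site <- enz$site[i]
      m <- Biostrings::matchPattern(site, subj, fixed = "subject")
      if (length(m) == 0) return(NULL)
      starts0 <- Biostrings::start(m) - 1L
      width <- nchar(site)
      # drop windows containing N (ambiguous reference); fixed="subject"
      # already refuses them, this is a guard for exotic subject codes
      has_n <- grepl("N", as.character(m), fixed = TRUE)
      starts0 <- starts0[!has_n]
      if (length(starts0) == 0) return(NULL)
      methylated <- if (length(meth_pos) == 0) {
        rep(FALSE, length(starts0))
      } else {
        vapply(starts0, function(s) any(meth_pos >= s & meth_pos < s + width), logical(1))
      }
      sens <- enz$methylation_sensitivity[i]
      keep <- rep(TRUE, length(starts0))
      if (sens == "full") {
        keep <- !methylated
      } else if (sens == "partial" && any(methylated)) {
        # deferred Bernoulli draw; marked here, drawn once below for
        # deterministic ordering across sequences and enzymes
        keep <- ifelse(methylated, NA, TRUE)
      }
      tibble::tibble(
        chrom = chrom,
        coordinate = starts0 + enz$cut_offset[i],
        enzyme = enz$name[i],
        site_start = starts0,
        .keep = keep
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(per_seq))
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), coordinate = integer(),
                          enzyme = character(), site_start = integer())
  } else {
    pending <- is.na(out$.keep)
    if (any(pending)) {
      draws <- with_seed_if(seed, runif(sum(pending)) >= partial_block_prob)
      out$.keep[pending] <- draws
    }
    out <- out[out$.keep, c("chrom", "coordinate", "enzyme", "site_start")]
    ord <- order(match(out$chrom, names(genome)), out$coordinate,
                 match(out$enzyme, enz$name))
    out <- out[ord, ]
  }
  attr(out, "enzyme_order") <- enz$name
  out
}

normalize_methylation <- function(methylation, genome) {
  if (is.null(methylation)) return(NULL)
  if (!is.data.frame(methylation) || !all(c("chrom", "pos") %in% names(methylation))) {
    abort("`methylation` must be a data frame with columns chrom and pos.",
          class = "gbs_bad_argument")
  }
  meth <- tibble::as_tibble(methylation)[, c("chrom", "pos")]
  meth$pos <- as.integer(meth$pos)
  lens <- genome_lengths(genome)
  unknown <- !(meth$chrom %in% names(lens))
  if (any(unknown)) {
    abort("Methylation track references sequences absent from the genome.",
          class = "gbs_bad_argument")
  }
  oob <- meth$pos < 0 | meth$pos >= lens[meth$chrom]
  if (any(oob)) {
    abort("Methylation positions out of sequence bounds.", class = "gbs_bad_argument")
  }
  # keep only positions whose reference base is a cytosine on either strand
  base <- vapply(seq_len(nrow(meth)), function(i) {
    as.character(Biostrings::subseq(genome[[meth$chrom[i]]], meth$pos[i] + 1L,
                                    meth$pos[i] + 1L))
  }, character(1))
  drop <- !(base %in% c("C", "G"))
  if (any(drop)) {
    warn(sprintf("%d methylation record(s) at non-C/G reference bases dropped.",
                 sum(drop)))
    meth <- meth[!drop, ]
  }
  meth
}

#' Assemble fragments from cut sites
#'
#' Cuts each genome sequence at the distinct cut coordinates and returns the
#' resulting fragment tiling: `k` distinct cuts on a sequence of length `L`
#' yield `k + 1` half-open fragments covering `[0, L)` exactly. Each
#' fragment end is labelled with the cutting enzyme, or `"TERMINUS"` at the
#' sequence ends. When two enzymes cut at the identical coordinate the
#' first-listed enzyme labels the boundary and a warning is issued.
#'
#' @inheritParams find_cut_sites
#' @param cut_sites A cut-site tibble from [find_cut_sites()].
#' @return A tibble with columns `chrom`, `start`, `end`, `width`, `left`,
#'   `right`.
#' @examples
#' g <- c(chr1 = "AACTGCAGTTCCGGAA")
#' digest(g, find_cut_sites(g, c("PstI", "MspI")))
#' @export
digest <- function(genome, cut_sites) {
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)
  enz_order <- attr(cut_sites, "enzyme_order") %||% unique(cut_sites$enzyme)

  if (nrow(cut_sites) > 0) {
    if (!all(cut_sites$chrom %in% names(lens))) {
      abort("Cut sites reference sequences absent from the genome.",
            class = "gbs_bad_argument")
    }
    if (any(cut_sites$coordinate < 0 | cut_sites$coordinate > lens[cut_sites$chrom])) {
      abort("Cut coordinates out of sequence bounds.", class = "gbs_bad_argument")
    }
    unsorted <- cut_sites |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(bad = is.unsorted(.data$coordinate), .groups = "drop")
    if (any(unsorted$bad)) {
      abort("Cut sites must be sorted by coordinate within each sequence.",
            class = "gbs_bad_argument")
    }
  }

  n_coincident <- 0L
  frags <- purrr::map(names(genome), function(chrom) {
    cs <- cut_sites[cut_sites$chrom == chrom, ]
    if (nrow(cs) > 0) {
      # collapse coincident coordinates: first enzyme in registry order wins
      cs <- cs[order(cs$coordinate, match(cs$enzyme, enz_order)), ]
      dup <- duplicated(cs$coordinate)
      if (any(dup)) n_coincident <<- n_coincident + sum(dup)
      cs <- cs[!dup, ]
    }
    coords <- cs$coordinate
    labels <- cs$enzyme
    bounds <- c(0L, coords, lens[[chrom]])
    left_lab <- c("TERMINUS", labels)
    right_lab <- c(labels, "TERMINUS")
    keep <- bounds[-length(bounds)] < bounds[-1]  # drop empty edge fragments
    tibble::tibble(
      chrom = chrom,
      start = bounds[-length(bounds)][keep],
      end = bounds[-1][keep],
      left = left_lab[keep],
      right = right_lab[keep]
    )
  })
  out <- dplyr::bind_rows(frags)
  if (n_coincident > 0) {
    warn(sprintf("%d coincident cut coordinate(s): boundary labelled by first-listed enzyme.",
                 n_coincident))
  }
  out$width <- out$end - out$start
  out[, c("chrom", "start", "end", "width", "left", "right")]
}

#' Digest a genome in one step
#'
#' Convenience wrapper running [find_cut_sites()] then [digest()].
#'
#' @inheritParams find_cut_sites
#' @return A fragment tibble (see [digest()]).
#' @export
digest_genome <- function(genome, enzymes, methylation = NULL,
                          partial_block_prob = 0.5, seed = NULL) {
  genome <- as_genome(genome)
  cs <- find_cut_sites(genome, enzymes, methylation = methylation,
                       partial_block_prob = partial_block_prob, seed = seed)
  digest(genome, cs)
}

#' Compare enzyme combinations by in-silico digestion
#'
#' Digests the genome with each candidate enzyme combination and tabulates
#' cut-site counts (per enzyme and combined), fragment counts, and mean
#' fragment lengths, per sequence and genome-wide. This is the screening
#' table used to rank combinations by how strongly they reduce the genome.
#'
#' @inheritParams find_cut_sites
#' @param combinations A list of enzyme selections (each a character vector
#'   of names or an enzyme table). List names label the output; unnamed
#'   entries are labelled by joining enzyme names with `+`.
#' @return A tibble with columns `combination`, `chrom` (`"(genome)"` for
#'   totals), `enzyme` (`"(combined)"` for the union), `n_cut_sites`,
#'   `n_fragments`, `mean_fragment_length` (fragment columns populated on
#'   `"(combined)"` rows).
#' @export
evaluate_combinations <- function(genome, combinations, methylation = NULL,
                                  partial_block_prob = 0.5, seed = NULL) {
  if (!is.list(combinations) || length(combinations) == 0) {
    abort("`combinations` must be a non-empty list of enzyme selections.",
          class = "gbs_bad_argument")
  }
  genome <- as_genome(genome)
  labels <- names(combinations) %||% rep(NA_character_, length(combinations))
  rows <- purrr::imap(combinations, function(combo, idx) {
    enz <- resolve_enzymes(combo)
    lab <- if (is.character(idx) && nzchar(idx)) idx else paste(enz$name, collapse = "+")
    cs <- find_cut_sites(genome, enz, methylation = methylation,
                         partial_block_prob = partial_block_prob, seed = seed)
    fr <- digest(genome, cs)
    per_enz <- cs |>
      dplyr::group_by(chrom = .data$chrom, enzyme = .data$enzyme) |>
      dplyr::summarise(n_cut_sites = dplyr::n(), .groups = "drop")
    per_enz_all <- cs |>
      dplyr::group_by(enzyme = .data$enzyme) |>
      dplyr::summarise(n_cut_sites = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(chrom = "(genome)")
    comb_chrom <- fr |>
      dplyr::group_by(chrom = .data$chrom) |>
      dplyr::summarise(n_fragments = dplyr::n(),
                       mean_fragment_length = mean(.data$width), .groups = "drop") |>
      dplyr::left_join(
        cs |> dplyr::group_by(chrom = .data$chrom) |>
          dplyr::summarise(n_cut_sites = dplyr::n(), .groups = "drop"),
        by = "chrom") |>
      dplyr::mutate(n_cut_sites = dplyr::coalesce(.data$n_cut_sites, 0L),
                    enzyme = "(combined)")
    comb_all <- tibble::tibble(
      chrom = "(genome)", enzyme = "(combined)",
      n_cut_sites = nrow(cs), n_fragments = nrow(fr),
      mean_fragment_length = mean(fr$width)
    )
    dplyr::bind_rows(per_enz, per_enz_all, comb_chrom, comb_all) |>
      dplyr::mutate(combination = lab)
  })
  dplyr::bind_rows(rows) |>
    dplyr::select("combination", "chrom", "enzyme", "n_cut_sites",
                  "n_fragments", "mean_fragment_length")
}

#' Write cut sites or fragments as BED
#'
#' Exports a cut-site tibble (zero-width intervals named by enzyme) or a
#' fragment tibble (intervals named `left-right`, score = fragment length)
#' as BED, 0-based half-open.
#'
#' @param x A tibble from [find_cut_sites()] or [digest()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (all(c("start", "end", "left", "right") %in% names(x))) {
    bed <- tibble::tibble(chrom = x$chrom, start = x$start, end = x$end,
                          name = paste0(x$left, "-", x$right),
                          score = x$width, strand = ".")
  } else if (all(c("coordinate", "enzyme") %in% names(x))) {
    bed <- tibble::tibble(chrom = x$chrom, start = x$coordinate,
                          end = x$coordinate, name = x$enzyme,
                          score = 0L, strand = ".")
  } else {
    abort("`x` must be a cut-site or fragment tibble.", class = "gbs_bad_argument")
  }
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
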