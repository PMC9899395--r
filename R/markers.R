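# Marker-distribution diagnostics: SNP densities and gap inventories on
# physical (bp) and genetic (cM) coordinates, and nearest-anchor placement
# of markers on a consensus genetic map.

# Shared engine for physical/genetic density-and-gap reports. `spans` is a
# named vector of per-chromosome total lengths in the working unit.
marker_report_engine <- function(markers, pos_col, spans, thresholds,
                                 density_unit, include_ends = FALSE) {
  if (is.null(names(spans))) {
    abort("Chromosome spans must be named.", class = "gbs_bad_argument")
  }
  unknown <- setdiff(unique(markers$chrom), names(spans))
  if (length(unknown) > 0) {
    abort(sprintf("Markers on chromosomes without a span: %s.",
                  paste(unknown, collapse = ", ")),
          class = "gbs_bad_argument")
  }
  if (any(markers[[pos_col]] > spans[markers$chrom] | markers[[pos_col]] < 0)) {
    abort("Marker positions beyond chromosome span.", class = "gbs_bad_argument")
  }
  per_chrom_gaps <- purrr::map(names(spans), function(ch) {
    p <- sort(markers[[pos_col]][markers$chrom == ch])
    if (length(p) == 0) return(NULL)
    from <- p[-length(p)]
    to <- p[-1]
    if (include_ends) {
      from <- c(0, from)
      to <- c(p[1], to)
      from <- c(from, p[length(p)])
      to <- c(to, spans[[ch]])
    }
    if (length(from) == 0) return(NULL)
    tibble::tibble(chrom = ch, from = from, to = to, width = to - from)
  })
  gap_tbl <- dplyr::bind_rows(per_chrom_gaps)
  if (nrow(gap_tbl) == 0) {
    gap_tbl <- tibble::tibble(chrom = character(), from = numeric(),
                              to = numeric(), width = numeric())
  }
  gaps <- purrr::map(thresholds, function(th) {
    hits <- gap_tbl[gap_tbl$width > th, , drop = FALSE]
    tibble::tibble(threshold = th, n_gaps = nrow(hits),
                   gaps = list(hits))
  }) |> dplyr::bind_rows()

  total_span <- sum(spans)
  density <- nrow(markers) / (total_span / density_unit)
  per_chromosome <- markers |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(n_markers = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(span = as.numeric(spans[.data$chrom]),
                  density = .data$n_markers / (.data$span / density_unit))
  summary <- tibble::tibble(
    n_markers = nrow(markers), total_span = total_span, density = density
  )
  structure(
    list(summary = summary, per_chromosome = per_chromosome, gaps = gaps,
         thresholds = thresholds, include_ends = include_ends,
         density_unit = density_unit),
    class = "gbs_marker_report"
  )
}

#' Physical marker density and gap inventory
#'
#' Computes genome-wide and per-chromosome SNP density (markers per Mb) and
#' counts inter-marker gaps: distances between consecutive markers on the
#' same chromosome strictly exceeding each threshold (defaults 5 Mb and
#' 10 Mb). Distances from chromosome ends to the first/last marker are not
#' counted as gaps unless `include_ends = TRUE`.
#'
#' @param markers A tibble with columns `chrom` and `pos` (bp).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param thresholds Gap thresholds in bp (default `c(5e6, 1e7)`).
#' @param include_ends Also treat the flanks before the first and after the
#'   last marker as gaps (default FALSE).
#' @return A `gbs_marker_report`: `summary` (density in SNP/Mb), a
#'   per-chromosome table, and per-threshold gap counts with gap locations.
#' @export
density_and_gaps <- function(markers, chrom_lengths, thresholds = c(5e6, 1e7),
                             include_ends = FALSE) {
  rep <- marker_report_engine(markers, "pos", chrom_lengths, thresholds,
                              density_unit = 1e6, include_ends = include_ends)
  rep$scale <- "physical"
  rep
}

#' Genetic marker density and gap inventory
#'
#' As [density_and_gaps()] but on centimorgan coordinates: density is
#' SNP/cM over the total map length, and gaps are consecutive-marker cM
#' distances exceeding the thresholds (defaults 10 and 20 cM).
#'
#' @param markers A tibble with columns `chrom` and `pos_cM`.
#' @param map_spans Named vector of per-chromosome map lengths in cM.
#' @param thresholds Gap thresholds in cM (default `c(10, 20)`).
#' @inheritParams density_and_gaps
#' @return A `gbs_marker_report` with density in SNP/cM.
#' @export
genetic_density_and_gaps <- function(markers, map_spans, thresholds = c(10, 20),
                                     include_ends = FALSE) {
  rep <- marker_report_engine(markers, "pos_cM", map_spans, thresholds,
                              density_unit = 1, include_ends = include_ends)
  rep$scale <- "genetic"
  rep
}

#' @export
print.gbs_marker_report <- function(x, ...) {
  unit <- if (identical(x$scale, "genetic")) "cM" else "Mb"
  cat("<gbs_marker_report>\n")
  cat(sprintf("  %d markers, density %.3g SNP/%s\n",
              x$summary$n_markers, x$summary$density, unit))
  for (i in seq_len(nrow(x$gaps))) {
    cat(sprintf("  gaps > %g %s: %d\n", x$gaps$threshold[i] /
                  (if (unit == "Mb") 1e6 else 1),
                unit, x$gaps$n_gaps[i]))
  }
  invisible(x)
}

#' Assign genetic positions from a consensus map
#'
#' Gives each marker the centimorgan position of the consensus-map anchor
#' with the smallest physical distance on the same chromosome; ties go to
#' the anchor at the smaller bp position. Markers on chromosomes absent
#' from the map are flagged unplaced (`placed = FALSE`, `pos_cM = NA`).
#'
#' @param markers A tibble with columns `chrom` and `pos` (bp).
#' @param map A consensus map tibble (`marker_id`, `chrom`, `pos_bp`,
#'   `pos_cM`), monotone in cM within each chromosome.
#' @return `markers` with added `pos_cM`, `anchor_id`, `placed` columns.
#' @export
assign_genetic_positions <- function(markers, map) {
  if (nrow(map) == 0) abort("Empty consensus map.", class = "gbs_bad_argument")
  out <- tibble::as_tibble(markers)
  out$pos_cM <- NA_real_
  out$anchor_id <- NA_character_
  out$placed <- FALSE
  for (ch in unique(out$chrom)) {
    anchors <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(anchors) == 0) next
    anchors <- anchors[order(anchors$pos_bp), , drop = FALSE]
    idx <- which(out$chrom == ch)
    q <- out$pos[idx]
    # nearest anchor via findInterval on sorted anchor bp; ties -> smaller bp
    lo <- findInterval(q, anchors$pos_bp)
    lo_idx <- pmax(lo, 1L)
    hi_idx <- pmin(lo + 1L, nrow(anchors))
    d_lo <- abs(q - anchors$pos_bp[lo_idx])
    d_hi <- abs(q - anchors$pos_bp[hi_idx])
    use_lo <- lo >= 1L & (d_lo <= d_hi | hi_idx == lo_idx)
    pick <- ifelse(use_lo, lo_idx, hi_idx)
    out$pos_cM[idx] <- anchors$pos_cM[pick]
    out$anchor_id[idx] <- anchors$marker_id[pick]
    out$placed[idx] <- TRUE
  }
  out
}
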