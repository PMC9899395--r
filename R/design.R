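# End-to-end protocol design: digest -> select -> predict -> budget, with a
# JSON report. This is the single call behind the command-line `run-design`
# entry point.

#' Run a full protocol design
#'
#' Digests the genome with the design's enzymes, selects
#' adapter-compatible fragments inside the size window, predicts genome
#' coverage and library composition, and evaluates the read budget at the
#' requested sequencing effort. Optionally writes the intermediate tables
#' (cut sites, fragments, selection) and a JSON design report with stable
#' file names under `out_dir`.
#'
#' @inheritParams find_cut_sites
#' @param design A [library_design()].
#' @param reads_per_sample Planned reads per sample for the budget model.
#' @param min_depth Minimum depth for a confident call (default 2).
#' @param run_capacity Optional reads per sequencing run.
#' @param out_dir Optional output directory for report files.
#' @return A `gbs_design_report` list: `prediction`
#'   (`gbs_library_prediction`), `budget` (`gbs_budget`), `parameters`, and
#'   `report` (the JSON-ready list).
#' @export
run_design <- function(genome, enzymes = c("PstI", "NsiI", "MspI"),
                       design = library_design(), reads_per_sample = 100000,
                       min_depth = 2, run_capacity = NULL, methylation = NULL,
                       partial_block_prob = 0.5, seed = NULL, out_dir = NULL) {
  genome <- as_genome(genome)
  enz <- resolve_enzymes(enzymes)
  cut_sites <- find_cut_sites(genome, enz, methylation = methylation,
                              partial_block_prob = partial_block_prob, seed = seed)
  fragments <- digest(genome, cut_sites)
  genome_length <- sum(genome_lengths(genome))
  prediction <- predict_library(fragments, design, genome_length)
  n_frag <- prediction$summary$n_selected
  budget <- if (n_frag > 0) {
    gbs_budget(n_frag, reads_per_sample = reads_per_sample,
               min_depth = min_depth, run_capacity = run_capacity)
  } else {
    NULL
  }
  parameters <- list(
    enzymes = enz$name,
    rare_set = design$rare_set,
    frequent_cutter = design$frequent_cutter,
    size_window = design$size_window,
    adapter_extension = design$adapter_extension,
    reads_per_sample = reads_per_sample,
    min_depth = min_depth,
    run_capacity = run_capacity,
    partial_block_prob = partial_block_prob,
    seed = seed,
    genome_length = genome_length,
    n_sequences = length(genome)
  )
  report <- list(
    parameters = parameters,
    prediction = c(as.list(prediction$summary),
                   list(pairs = prediction$pairs,
                        per_chromosome = prediction$per_chromosome)),
    budget = if (is.null(budget)) NULL else as.list(budget$summary)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(cut_sites, file.path(out_dir, "cut_sites.bed"))
    write_bed(fragments, file.path(out_dir, "fragments.bed"))
    write_bed(prediction$selected[, setdiff(names(prediction$selected), "pair")],
              file.path(out_dir, "selected_fragments.bed"))
    jsonlite::write_json(report, file.path(out_dir, "design_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  structure(
    list(prediction = prediction, budget = budget, cut_sites = cut_sites,
         fragments = fragments, parameters = parameters, report = report),
    class = "gbs_design_report"
  )
}

#' @export
print.gbs_design_report <- function(x, ...) {
  cat("<gbs_design_report>\n")
  print(x$prediction)
  if (!is.null(x$budget)) print(x$budget)
  invisible(x)
}
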