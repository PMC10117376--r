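# End-to-end AP-MS pipeline: score filtering, hit extraction, funnel,
# abundance of the final interactome.

#' Run the AP-MS interactome pipeline
#'
#' Applies the Mascot score filter to every PSM table, derives
#' per-replicate hit lists, runs the filtering funnel (contaminants,
#' control subtraction, CRAPome, replicate intersection), and computes
#' the emPAI abundance table for the final interactome.
#'
#' @param bait_psms Named list of bait PSM tables (one per replicate).
#' @param control_psms List of matched control PSM tables (same order).
#' @param observable_counts Data frame `protein_id`, `n_observable`.
#' @param occ Control-occurrence matrix/table.
#' @param contaminant_set Known-contaminant symbols.
#' @param min_score Mascot threshold (default 40).
#' @param max_occurrence CRAPome occurrence tolerance (default 1).
#' @return List with `interactome` (character vector), `abundance`
#'   (restricted to the final set, re-ranked), `funnel` (data frame) and
#'   `reports`.
#' @export
run_apms_pipeline <- function(bait_psms, control_psms, observable_counts, occ,
                              contaminant_set = default_contaminants(),
                              min_score = 40, max_occurrence = 1L) {
  bait_f <- lapply(bait_psms, filter_psms, min_score = min_score)
  ctrl_f <- lapply(control_psms, filter_psms, min_score = min_score)
  bait_hits <- lapply(bait_f, function(d) sort(unique(d$protein_id)))
  ctrl_hits <- lapply(ctrl_f, function(d) sort(unique(d$protein_id)))
  fn <- filter_funnel(bait_hits, ctrl_hits, occ,
                      contaminant_set = contaminant_set,
                      max_occurrence = max_occurrence)
  bait_final <- lapply(bait_f, function(d) d[d$protein_id %in% fn$final, , drop = FALSE])
  abundance <- protein_abundance(bait_final,
                                 observable_counts[observable_counts$protein_id %in% fn$final, , drop = FALSE])
  list(interactome = fn$final, abundance = abundance,
       funnel = fn$funnel, reports = fn$reports)
}
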