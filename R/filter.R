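# The interactome filtering funnel: known contaminants, control subtraction,
# CRAPome exclusion, replicate intersection. All stages are pure set logic;
# the published procedure filters on detection, not enrichment.

filter_report <- function(stage, hits_in, hits_out) {
  removed <- setdiff(hits_in, hits_out)
  structure(list(stage = stage,
                 n_in = length(hits_in),
                 n_out = length(hits_out),
                 removed_ids = sort(removed),
                 retention_fraction = if (length(hits_in) > 0)
                   length(hits_out) / length(hits_in) else NA_real_),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("[%s] %d -> %d (%.1f%% retained, %d removed)\n",
              x$stage, x$n_in, x$n_out,
              100 * x$retention_fraction, length(x$removed_ids)))
  invisible(x)
}

#' Packaged default contaminant list
#'
#' Keratins, bovine serum proteins introduced during cell culture, and
#' trypsin used for fragmentation -- the standard AP-MS contaminant classes.
#'
#' @return Character vector of contaminant gene symbols.
#' @export
default_contaminants <- function() {
  path <- system.file("extdata", "contaminants.txt", package = "ppikit")
  canonical_symbol(readLines(path, warn = FALSE))
}

#' Remove known contaminant proteins
#'
#' @param hits Character vector of protein symbols.
#' @param contaminant_set Symbols to remove; defaults to the packaged
#'   keratin/bovine/trypsin list.
#' @return List with `hits` (filtered, sorted) and `report`
#'   (a `filter_report`).
#' @export
remove_known_contaminants <- function(hits, contaminant_set = default_contaminants()) {
  hits <- canonical_symbol(unique(hits))
  out <- sort(setdiff(hits, canonical_symbol(contaminant_set)))
  list(hits = out, report = filter_report("contaminants", hits, out))
}

#' Subtract control-detected proteins
#'
#' Removes every protein that was detected in the matched control
#' purification, regardless of abundance.
#'
#' @param bait_hits,control_hits Character vectors of protein symbols from
#'   the same replicate.
#' @return List with `hits` and `report`.
#' @export
subtract_control <- function(bait_hits, control_hits) {
  bait_hits <- canonical_symbol(unique(bait_hits))
  out <- sort(setdiff(bait_hits, canonical_symbol(control_hits)))
  list(hits = out, report = filter_report("control_subtraction", bait_hits, out))
}

#' Collapse a wide control-occurrence matrix to occurrence counts
#'
#' @param occ_matrix Data frame with a `protein_id` column followed by one
#'   binary column per negative-control experiment.
#' @return Data frame with `protein_id`, `occurrence`, `n_controls`.
#' @export
occurrence_counts <- function(occ_matrix) {
  stopifnot(is.data.frame(occ_matrix), "protein_id" %in% names(occ_matrix))
  cols <- setdiff(names(occ_matrix), "protein_id")
  data.frame(protein_id = canonical_symbol(occ_matrix$protein_id),
             occurrence = as.integer(rowSums(occ_matrix[cols] > 0)),
             n_controls = length(cols),
             stringsAsFactors = FALSE)
}

#' CRAPome-style frequent-flyer exclusion
#'
#' Excludes proteins that occurred in more than `max_occurrence` of the
#' negative-control experiments (default: more than 1 of the matched
#' controls). Proteins absent from the matrix count as occurrence 0.
#'
#' @param hits Character vector of protein symbols.
#' @param occ Occurrence table (`protein_id`, `occurrence`) or a wide
#'   binary matrix as produced by [gen_control_occurrence()].
#' @param max_occurrence Maximum tolerated control occurrence (default 1).
#' @return List with `hits` and `report`.
#' @export
crapome_filter <- function(hits, occ, max_occurrence = 1L) {
  hits <- canonical_symbol(unique(hits))
  if (!"occurrence" %in% names(occ)) occ <- occurrence_counts(occ)
  counts <- stats::setNames(occ$occurrence, canonical_symbol(occ$protein_id))
  hit_occ <- counts[hits]
  hit_occ[is.na(hit_occ)] <- 0L
  out <- sort(hits[hit_occ <= max_occurrence])
  list(hits = out, report = filter_report("crapome", hits, out))
}

#' Intersect replicate hit lists
#'
#' Only proteins replicated in every independent AP-MS experiment are kept.
#' Per-replicate retention fractions support funnel-style reporting
#' (final-set size over per-replicate size).
#'
#' @param per_replicate_hits List (>= 2) of character vectors.
#' @return List with `hits` (the intersection) and `reports`, one
#'   `filter_report` per replicate.
#' @export
intersect_replicates <- function(per_replicate_hits) {
  if (!is.list(per_replicate_hits) || length(per_replicate_hits) < 2L) {
    stopf("replicate intersection needs at least 2 hit lists")
  }
  lists <- lapply(per_replicate_hits, function(h) canonical_symbol(unique(h)))
  if (is.null(names(lists)) || any(names(lists) == "")) {
    names(lists) <- paste0("AP", seq_along(lists))
  }
  final <- sort(Reduce(intersect, lists))
  reports <- lapply(names(lists), function(nm) {
    filter_report(paste0("replicate_intersection:", nm), lists[[nm]], final)
  })
  names(reports) <- names(lists)
  list(hits = final, reports = reports)
}

#' Run the full filtering funnel
#'
#' Applies, per replicate and in order: known-contaminant removal, control
#' subtraction, CRAPome exclusion; then intersects replicates. The funnel
#' table reports, for every stage of every replicate, counts and the
#' percentage of the original hit list remaining (half-up integer percent),
#' matching the way AP-MS filtering funnels are published.
#'
#' @param bait_hits Named list of per-replicate bait hit lists.
#' @param control_hits List of matched control hit lists (same order).
#' @param occ Control-occurrence table or matrix.
#' @param contaminant_set Contaminant symbols (packaged default).
#' @param max_occurrence CRAPome occurrence tolerance (default 1).
#' @return List with `final` (character vector), `funnel` (data frame), and
#'   `reports` (nested `filter_report`s).
#' @export
filter_funnel <- function(bait_hits, control_hits, occ,
                          contaminant_set = default_contaminants(),
                          max_occurrence = 1L) {
  if (length(bait_hits) != length(control_hits)) {
    stopf("need one control hit list per bait replicate")
  }
  if (is.null(names(bait_hits)) || any(names(bait_hits) == "")) {
    names(bait_hits) <- paste0("AP", seq_along(bait_hits))
  }
  reports <- list()
  staged <- list()
  for (nm in names(bait_hits)) {
    r1 <- remove_known_contaminants(bait_hits[[nm]], contaminant_set)
    r2 <- subtract_control(r1$hits, control_hits[[match(nm, names(bait_hits))]])
    r3 <- crapome_filter(r2$hits, occ, max_occurrence)
    reports[[nm]] <- list(contaminants = r1$report,
                          control_subtraction = r2$report,
                          crapome = r3$report)
    staged[[nm]] <- r3$hits
  }
  ix <- intersect_replicates(staged)
  for (nm in names(bait_hits)) reports[[nm]]$replicate_intersection <- ix$reports[[nm]]

  rows <- list()
  for (nm in names(bait_hits)) {
    n0 <- length(unique(canonical_symbol(bait_hits[[nm]])))
    for (rep in reports[[nm]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = nm, stage = rep$stage, n_in = rep$n_in, n_out = rep$n_out,
        pct_of_original = percent_int(rep$n_out, n0),
        stringsAsFactors = FALSE)
    }
  }
  list(final = ix$hits,
       funnel = do.call(rbind, rows),
       reports = reports)
}
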