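# Peptide-level Mascot filtering and protein-level emPAI abundance.

#' Convert a Mascot score to its match probability
#'
#' A Mascot ion score is `-10 * log10(P)` where `P` is the probability that
#' the observed peptide-spectrum match is a random event. The conventional
#' identity threshold of 40 therefore corresponds to `P = 1e-4`.
#'
#' @param score Non-negative numeric vector of Mascot scores.
#' @return Probabilities in `(0, 1]`.
#' @seealso [score_from_probability()] for the inverse.
#' @export
#' @examples
#' mascot_probability(40) # 1e-4
mascot_probability <- function(score) {
  if (any(is.na(score)) || !is.numeric(score) || any(score < 0)) {
    stopf("Mascot scores must be non-negative numbers")
  }
  10^(-score / 10)
}

#' Convert a match probability to a Mascot score
#'
#' @param p Probability vector in `(0, 1]`.
#' @return Mascot scores (`-10 * log10(p)`).
#' @export
score_from_probability <- function(p) {
  if (any(is.na(p)) || !is.numeric(p) || any(p <= 0) || any(p > 1)) {
    stopf("probabilities must lie in (0, 1]")
  }
  -10 * log10(p)
}

#' Filter peptide-spectrum matches by Mascot score
#'
#' Removes rows whose `mascot_score` is strictly below `min_score`
#' (score 40 and above is retained at the default threshold). Row order is
#' preserved and the operation is idempotent.
#'
#' @param psm Data frame with at least a numeric `mascot_score` column.
#' @param min_score Score threshold, default 40 (`P = 1e-4`).
#' @return The filtered data frame.
#' @export
filter_psms <- function(psm, min_score = 40) {
  if (!is.data.frame(psm) || !"mascot_score" %in% names(psm)) {
    stopf("'psm' must be a data frame with a 'mascot_score' column")
  }
  out <- psm[psm$mascot_score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exponentially modified protein abundance index
#'
#' `emPAI = 10^(n_observed / n_observable) - 1`, where `n_observed` is the
#' number of distinct peptides identified for the protein and `n_observable`
#' the theoretical number of peptides in the preferred mass range. The index
#' normalizes spectral evidence by protein size, giving a label-free
#' relative abundance estimate.
#'
#' @param n_observed Count(s) of distinct observed peptides.
#' @param n_observable Count(s) of theoretically observable peptides (>= 1).
#' @return Non-negative emPAI value(s).
#' @export
#' @examples
#' compute_empai(5, 5)  # 9
#' compute_empai(1, 2)  # 10^0.5 - 1
compute_empai <- function(n_observed, n_observable) {
  if (any(is.na(n_observable)) || any(n_observable < 1)) {
    stopf("'n_observable' must be >= 1 for every protein")
  }
  if (any(is.na(n_observed)) || any(n_observed < 0)) {
    stopf("'n_observed' must be non-negative")
  }
  10^(n_observed / n_observable) - 1
}

#' Per-experiment and mean emPAI abundance table
#'
#' Counts distinct peptide sequences per protein within each experiment
#' (the score filter is assumed to have been applied already), converts the
#' counts to emPAI, and averages across experiments. A protein absent from
#' an experiment contributes emPAI 0 for that experiment, so the mean
#' penalizes non-replicated hits. Proteins are ranked by mean emPAI
#' descending, ties broken lexicographically by symbol; proteins with mean
#' emPAI > 1 are flagged as high abundance.
#'
#' @param psms_by_experiment Named list of filtered PSM data frames (columns
#'   `protein_id`, `peptide_seq`), one per experiment. Names label the
#'   per-experiment emPAI columns.
#' @param observable_counts Data frame with columns `protein_id`,
#'   `n_observable` covering every protein in the PSM tables.
#' @return Data frame with columns `protein_id`, one `empai_<experiment>`
#'   column per experiment, `mean_empai`, `rank`, `high_abundance`.
#' @export
protein_abundance <- function(psms_by_experiment, observable_counts) {
  if (!is.list(psms_by_experiment) || length(psms_by_experiment) < 1L) {
    stopf("'psms_by_experiment' must be a non-empty list of PSM tables")
  }
  if (is.null(names(psms_by_experiment)) || any(names(psms_by_experiment) == "")) {
    names(psms_by_experiment) <- paste0("AP", seq_along(psms_by_experiment))
  }
  proteins <- sort(unique(unlist(lapply(psms_by_experiment, function(d) d$protein_id))))
  if (length(proteins) == 0L) {
    return(data.frame(protein_id = character(), mean_empai = numeric(),
                      rank = integer(), high_abundance = logical(),
                      stringsAsFactors = FALSE))
  }
  missing <- setdiff(proteins, observable_counts$protein_id)
  if (length(missing) > 0L) {
    stopf("proteins missing from observable_counts: %s",
          paste(missing, collapse = ", "))
  }
  n_obsbl <- stats::setNames(observable_counts$n_observable,
                             observable_counts$protein_id)[proteins]

  empai <- sapply(psms_by_experiment, function(d) {
    n_obs <- vapply(proteins, function(p) {
      length(unique(d$peptide_seq[d$protein_id == p]))
    }, integer(1))
    compute_empai(n_obs, n_obsbl)
  })
  empai <- matrix(empai, nrow = length(proteins),
                  dimnames = list(proteins, names(psms_by_experiment)))

  mean_empai <- rowMeans(empai)   # absence already contributes 0
  ord <- order(-mean_empai, proteins)
  rank <- integer(length(proteins))
  rank[ord] <- seq_along(ord)

  out <- data.frame(protein_id = proteins, stringsAsFactors = FALSE)
  for (exp in colnames(empai)) out[[paste0("empai_", exp)]] <- empai[, exp]
  out$mean_empai <- mean_empai
  out$rank <- rank
  out$high_abundance <- mean_empai > 1
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hit list of an experiment
#'
#' Proteins with at least one peptide passing the score filter.
#'
#' @param psm PSM data frame.
#' @param min_score Mascot score threshold.
#' @return Sorted character vector of protein symbols.
#' @export
psm_hits <- function(psm, min_score = 40) {
  sort(unique(filter_psms(psm, min_score)$protein_id))
}
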