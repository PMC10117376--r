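# Corrected BRET ratios, one-way ANOVA with Tukey HSD post-hoc tests,
# and interaction calling for wild-type and variant proteins.
#
# A BRET plate is a data frame with columns:
#   well, condition (experimental / donor_only_control / untransfected),
#   construct_pair (label of the donor/acceptor pair; the donor-only
#   control carries its own label, e.g. "Rluc-NLS"), Blue1, Green1.

check_plate <- function(plate) {
  need <- c("well", "condition", "construct_pair", "Blue1", "Green1")
  if (!is.data.frame(plate) || !all(need %in% names(plate))) {
    stopf("a BRET plate needs columns %s", paste(need, collapse = ", "))
  }
  invisible(plate)
}

#' Read a BRET plate CSV
#'
#' @param path CSV path with columns `well`, `condition`,
#'   `construct_pair`, `Blue1`, `Green1`.
#' @return Plate data frame.
#' @export
read_plate <- function(path) {
  check_plate(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Subtract untransfected background from plate readings
#'
#' The per-channel mean of the untransfected wells is subtracted from
#' every other well; results below 0 are floored at 0 (negative
#' luminescence is not propagated) and the floored-well count is recorded
#' in the `floored` attribute.
#'
#' @param plate BRET plate data frame.
#' @return Background-corrected plate (untransfected wells removed).
#' @export
background_correct <- function(plate) {
  check_plate(plate)
  bg <- plate$condition == "untransfected"
  if (!any(bg)) stopf("no untransfected background wells on the plate")
  bg_blue <- mean(plate$Blue1[bg])
  bg_green <- mean(plate$Green1[bg])
  out <- plate[!bg, , drop = FALSE]
  blue <- out$Blue1 - bg_blue
  green <- out$Green1 - bg_green
  floored <- sum(blue < 0) + sum(green < 0)
  if (floored > 0L) {
    warnf("%d channel reading(s) fell below background and were floored at 0", floored)
  }
  out$Blue1 <- pmax(blue, 0)
  out$Green1 <- pmax(green, 0)
  rownames(out) <- NULL
  attr(out, "floored") <- floored
  out
}

#' Per-well corrected BRET ratios
#'
#' For every non-background well, `Green1/Blue1` minus the mean
#' `Green1/Blue1` of the donor-only control wells on the plate (the plate
#' mean of the control ratio is used; wells are not paired). The
#' donor-only wells themselves are reported too, centered on 0, so they
#' can serve as the control group in downstream ANOVA. Wells with
#' `Blue1 = 0` are excluded with a warning.
#'
#' @param plate Background-corrected plate (see [background_correct()]).
#' @return Data frame `construct_pair`, `well`, `ratio`.
#' @export
corrected_ratio <- function(plate) {
  check_plate(plate)
  donor <- plate$condition == "donor_only_control"
  if (!any(donor)) stopf("no donor-only control wells on the plate")
  usable <- plate$Blue1 > 0
  if (any(!usable)) {
    warnf("%d well(s) with Blue1 = 0 excluded from ratio computation", sum(!usable))
  }
  if (!any(usable)) stopf("all wells excluded: no Blue1 signal")
  if (!any(usable & donor)) stopf("all donor-only control wells excluded")
  raw <- plate$Green1 / plate$Blue1
  ctrl_mean <- mean(raw[donor & usable])
  out <- data.frame(construct_pair = plate$construct_pair[usable],
                    well = plate$well[usable],
                    ratio = raw[usable] - ctrl_mean,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Computes the one-way ANOVA F statistic and all pairwise comparisons
#' adjusted by Tukey's honestly-significant-difference procedure
#' (Tukey-Kramer for unbalanced groups), using the studentized range
#' distribution.
#'
#' @param groups Named list (>= 2) of numeric replicate vectors, each of
#'   length >= 2.
#' @return List with `f_statistic`, `df` (between, within), `p_value`
#'   (omnibus), and `pairs`: data frame `group1`, `group2`, `diff`
#'   (group2 - group1), `se`, `p_adj`.
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stopf("ANOVA needs at least 2 groups")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stopf("groups must be named")
  }
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) {
    stopf("group '%s' has fewer than 2 replicates", names(groups)[sizes < 2L][1])
  }
  k <- length(groups)
  n <- sum(sizes)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / n
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L
  df2 <- n - k
  mse <- ss_within / df2
  f_stat <- if (mse > 0) (ss_between / df1) / mse else Inf
  p_omni <- if (is.finite(f_stat)) stats::pf(f_stat, df1, df2, lower.tail = FALSE) else 0

  nm <- names(groups)
  combs <- utils::combn(nm, 2)
  pairs <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                      stringsAsFactors = FALSE)
  pairs$diff <- means[pairs$group2] - means[pairs$group1]
  pairs$se <- sqrt(mse / 2 * (1 / sizes[pairs$group1] + 1 / sizes[pairs$group2]))
  q_obs <- ifelse(pairs$se > 0, abs(pairs$diff) / pairs$se, ifelse(pairs$diff == 0, 0, Inf))
  pairs$p_adj <- ifelse(is.infinite(q_obs), 0,
                        stats::ptukey(q_obs, nmeans = k, df = df2, lower.tail = FALSE))
  pairs$p_adj[q_obs == 0] <- 1
  rownames(pairs) <- NULL
  list(f_statistic = f_stat, df = c(between = df1, within = df2),
       p_value = p_omni, pairs = pairs)
}

tukey_p_vs <- function(tukey, a, b) {
  p <- tukey$pairs
  hit <- (p$group1 == a & p$group2 == b) | (p$group1 == b & p$group2 == a)
  if (!any(hit)) stopf("no Tukey comparison between '%s' and '%s'", a, b)
  p$p_adj[hit][1]
}

significance_tier <- function(p, alphas = c(0.05, 0.01, 0.001)) {
  alphas <- sort(alphas, decreasing = TRUE)
  tier <- "ns"
  stars <- c("*", "**", "***")
  for (i in seq_along(alphas)) if (p < alphas[i]) tier <- stars[i]
  tier
}

#' Call interactions from per-pair corrected ratios
#'
#' Each construct pair is compared to the donor-only control group with a
#' Tukey-adjusted p-value; significance tiers use strict inequalities
#' (`* p < 0.05`, `** p < 0.01`, `*** p < 0.001`). A pair is flagged as a
#' headline-positive interaction when its mean corrected ratio exceeds the
#' control mean and the adjusted p-value is below `headline_alpha`
#' (default 0.001).
#'
#' @param ratios Data frame from [corrected_ratio()].
#' @param control_label Construct label of the donor-only control
#'   (default `"Rluc-NLS"`).
#' @param alphas Tier thresholds.
#' @param headline_alpha Positivity threshold (default 0.001).
#' @return Data frame `construct_pair`, `n`, `mean`, `sd`,
#'   `p_vs_control`, `tier`, `positive`; the full Tukey result is in the
#'   `tukey` attribute.
#' @export
call_interaction <- function(ratios, control_label = "Rluc-NLS",
                             alphas = c(0.05, 0.01, 0.001),
                             headline_alpha = 0.001) {
  groups <- split(ratios$ratio, ratios$construct_pair)
  if (!control_label %in% names(groups)) {
    stopf("control group '%s' not found on the plate", control_label)
  }
  tk <- anova_tukey(groups)
  test_pairs <- setdiff(names(groups), control_label)
  ctrl_mean <- mean(groups[[control_label]])
  out <- data.frame(
    construct_pair = test_pairs,
    n = vapply(groups[test_pairs], length, integer(1)),
    mean = vapply(groups[test_pairs], mean, numeric(1)),
    sd = vapply(groups[test_pairs], stats::sd, numeric(1)),
    p_vs_control = vapply(test_pairs, function(g) tukey_p_vs(tk, g, control_label),
                          numeric(1)),
    stringsAsFactors = FALSE)
  out$tier <- vapply(out$p_vs_control, significance_tier, character(1), alphas = alphas)
  out$positive <- out$p_vs_control < headline_alpha & out$mean > ctrl_mean
  rownames(out) <- NULL
  attr(out, "tukey") <- tk
  out
}

#' Analyze a full BRET screening plate
#'
#' Background-corrects the plate, computes corrected ratios, and calls
#' interactions against the donor-only control.
#'
#' @param plate Raw plate data frame (with untransfected wells).
#' @param control_label Donor-only control construct label.
#' @param ... Passed to [call_interaction()].
#' @return The [call_interaction()] result.
#' @export
bret_screen <- function(plate, control_label = "Rluc-NLS", ...) {
  corrected <- background_correct(plate)
  ratios <- corrected_ratio(corrected)
  call_interaction(ratios, control_label = control_label, ...)
}

#' Classify a variant's effect on one interaction
#'
#' Decision rule (alpha default 0.05, Tukey-adjusted): *abolished* when the
#' variant signal is not significantly above the acceptor-dead control;
#' *reduced* when significant versus control but also significantly lower
#' than the wild-type protein; *retained* otherwise.
#'
#' @param variant_ratios Numeric corrected ratios for the variant.
#' @param wt_ratios Numeric corrected ratios for the wild-type protein.
#' @param control_ratios Numeric corrected ratios for the control fusion.
#' @param alpha Significance level (default 0.05).
#' @return List `class`, `p_vs_control`, `p_vs_wt`.
#' @export
classify_variant <- function(variant_ratios, wt_ratios, control_ratios,
                             alpha = 0.05) {
  if (length(wt_ratios) < 2L) stopf("missing or degenerate WT group")
  tk <- anova_tukey(list(variant = variant_ratios, wt = wt_ratios,
                         control = control_ratios))
  variant_class_rule(mean(variant_ratios), mean(wt_ratios),
                     mean(control_ratios),
                     tukey_p_vs(tk, "variant", "control"),
                     tukey_p_vs(tk, "variant", "wt"), alpha)
}

variant_class_rule <- function(mean_v, mean_wt, mean_ctrl, p_ctrl, p_wt, alpha) {
  sig_ctrl <- p_ctrl < alpha && mean_v > mean_ctrl
  lower_wt <- p_wt < alpha && mean_v < mean_wt
  cls <- if (!sig_ctrl) "abolished" else if (lower_wt) "reduced" else "retained"
  list(class = cls, p_vs_control = p_ctrl, p_vs_wt = p_wt)
}

#' Build a variant-by-interactor call matrix from plates
#'
#' Each plate tests one interactor against the wild-type protein, a panel
#' of variants, and a control fusion. Group labels on the plate must be
#' the control label, `wt_label`, and variant ids. A single one-way ANOVA
#' with Tukey post-hoc is fitted per plate across all groups (the
#' published design), so the error variance is pooled over the whole
#' plate rather than per variant triple.
#'
#' @param plates Named list of raw plates, one per interactor.
#' @param wt_label Construct label of the wild-type group (default "WT").
#' @param control_label Control fusion label (default "YFP-NLS"; the
#'   control construct differs between screen and variant assays, so it is
#'   a parameter, not a constant).
#' @param alpha Significance level for classification.
#' @return Data frame `variant`, `interactor`, `class`, `p_vs_control`,
#'   `p_vs_wt`.
#' @export
variant_call_matrix <- function(plates, wt_label = "WT",
                                control_label = "YFP-NLS", alpha = 0.05) {
  rows <- list()
  for (interactor in names(plates)) {
    corrected <- background_correct(plates[[interactor]])
    ratios <- corrected_ratio(corrected)
    groups <- split(ratios$ratio, ratios$construct_pair)
    if (!wt_label %in% names(groups)) stopf("missing WT group on plate '%s'", interactor)
    if (!control_label %in% names(groups)) {
      stopf("missing control group '%s' on plate '%s'", control_label, interactor)
    }
    tk <- anova_tukey(groups)
    for (v in setdiff(names(groups), c(wt_label, control_label))) {
      cl <- variant_class_rule(mean(groups[[v]]), mean(groups[[wt_label]]),
                               mean(groups[[control_label]]),
                               tukey_p_vs(tk, v, control_label),
                               tukey_p_vs(tk, v, wt_label), alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, interactor = interactor, class = cl$class,
        p_vs_control = cl$p_vs_control, p_vs_wt = cl$p_vs_wt,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
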