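test_that("background correction subtracts channel means and floors at zero", {
  plate <- manual_plate(
    list("W1", "untransfected", "none", 100, 50),
    list("W2", "donor_only_control", "Rluc-NLS", 1100, 550),
    list("W3", "experimental", "X", 1100, 550),
    list("W4", "experimental", "Y", 50, 10))       # below background
  expect_warning(out <- background_correct(plate), "floored")
  expect_equal(out$Blue1[out$construct_pair == "X"], 1000)
  expect_equal(out$Green1[out$construct_pair == "X"], 500)
  expect_equal(out$Blue1[out$construct_pair == "Y"], 0)
  expect_equal(out$Green1[out$construct_pair == "Y"], 0)
  expect_equal(attr(out, "floored"), 2L)
  expect_error(background_correct(plate[-1, ]), "untransfected")
})

test_that("corrected ratios subtract the donor-only plate mean", {
  plate <- manual_plate(
    list("W1", "donor_only_control", "Rluc-NLS", 10000, 4000),
    list("W2", "donor_only_control", "Rluc-NLS", 20000, 8000),
    list("W3", "experimental", "X", 10000, 5000),
    list("W4", "experimental", "Y", 10000, 4000))
  r <- corrected_ratio(plate)
  expect_equal(r$ratio[r$construct_pair == "X"], 0.1)
  expect_equal(r$ratio[r$construct_pair == "Y"], 0)   # identical to control
  expect_equal(mean(r$ratio[r$construct_pair == "Rluc-NLS"]), 0)
  # Blue1 = 0 wells excluded with a warning; all-excluded errors
  plate$Blue1[3] <- 0
  expect_warning(r2 <- corrected_ratio(plate), "excluded")
  expect_false("X" %in% r2$construct_pair)
  plate$Blue1 <- 0
  expect_error(suppressWarnings(corrected_ratio(plate)), "excluded|signal")
})

test_that("anova_tukey matches stats::TukeyHSD numerically", {
  set.seed(5)
  groups <- list(a = rnorm(4), b = rnorm(4, 1), c = rnorm(5, 0.5),
                 d = rnorm(3, 2))
  tk <- anova_tukey(groups)
  df <- data.frame(y = unlist(groups),
                   g = rep(names(groups), lengths(groups)))
  ref <- stats::TukeyHSD(stats::aov(y ~ g, data = df))$g
  for (i in seq_len(nrow(tk$pairs))) {
    key <- paste(tk$pairs$group2[i], tk$pairs$group1[i], sep = "-")
    expect_equal(tk$pairs$p_adj[i], unname(ref[key, "p adj"]),
                 tolerance = 1e-6, info = key)
    expect_equal(tk$pairs$diff[i], unname(ref[key, "diff"]), tolerance = 1e-9)
  }
  # omnibus F agrees with aov
  expect_equal(tk$f_statistic,
               summary(stats::aov(y ~ g, data = df))[[1]]$`F value`[1],
               tolerance = 1e-9)
})

test_that("anova_tukey handles null and near-degenerate groups", {
  expect_gt(anova_tukey(list(a = c(1, 2, 3), b = c(1, 2, 3)))$pairs$p_adj, 0.99)
  tk <- anova_tukey(list(a = c(0, 0, 0), b = c(10, 10, 10.0001)))
  expect_lt(tk$pairs$p_adj, 0.001)
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "'a'")
  expect_error(anova_tukey(list(a = c(1, 2))), "at least 2")
})

test_that("anova_tukey is invariant to label permutation and location shift", {
  set.seed(11)
  groups <- list(g1 = rnorm(3), g2 = rnorm(3, 0.8), g3 = rnorm(3, 0.2))
  tk1 <- anova_tukey(groups)
  tk2 <- anova_tukey(groups[c(3, 1, 2)])
  tk3 <- anova_tukey(lapply(groups, function(g) g + 5))
  pmap <- function(tk) {
    key <- paste(pmin(tk$pairs$group1, tk$pairs$group2),
                 pmax(tk$pairs$group1, tk$pairs$group2))
    stats::setNames(tk$pairs$p_adj, key)[order(key)]
  }
  expect_equal(pmap(tk1), pmap(tk2), tolerance = 1e-12)
  expect_equal(pmap(tk1), pmap(tk3), tolerance = 1e-9)
})

test_that("Tukey p-values agree with a label-permutation oracle", {
  set.seed(23)
  groups <- list(a = rnorm(8, 0, 1), b = rnorm(8, 1.1, 1), c = rnorm(8, 0.4, 1))
  tk <- anova_tukey(groups)
  p_impl <- tk$pairs$p_adj[tk$pairs$group1 == "a" & tk$pairs$group2 == "b"]
  set.seed(91)
  p_perm <- oracle_perm_tukey(groups, "a", "b", B = 3000)
  # studentized-range vs exchangeability null: agreement within Monte-Carlo
  # and small-sample approximation error
  expect_lt(abs(p_impl - p_perm), 0.05)
})

test_that("interaction calls use strict tier thresholds and a headline flag", {
  # build ratios with known separations around a near-zero control
  mk <- function(label, center) data.frame(construct_pair = label,
                                           well = paste0(label, 1:3),
                                           ratio = center + c(-0.01, 0, 0.01))
  ratios <- rbind(mk("Rluc-NLS", 0), mk("STRONG", 0.5), mk("NONE", 0.001))
  res <- call_interaction(ratios)
  strong <- res[res$construct_pair == "STRONG", ]
  expect_equal(strong$tier, "***")
  expect_true(strong$positive)
  none <- res[res$construct_pair == "NONE", ]
  expect_equal(none$tier, "ns")
  expect_false(none$positive)
  expect_error(call_interaction(ratios, control_label = "MISSING"), "control")
  # boundary semantics: p exactly at a threshold stays in the lower tier
  expect_equal(ppikit:::significance_tier(0.05), "ns")
  expect_equal(ppikit:::significance_tier(0.016), "*")
  expect_equal(ppikit:::significance_tier(0.0005), "***")
})

test_that("variant classification follows the control/WT decision rule", {
  ctrl <- c(-0.01, 0, 0.01)
  wt <- c(0.49, 0.5, 0.51)
  # not significant vs control -> abolished
  expect_equal(classify_variant(ctrl + 0.001, wt, ctrl)$class, "abolished")
  # significant vs control and significantly below WT -> reduced
  expect_equal(classify_variant(c(0.19, 0.2, 0.21), wt, ctrl)$class, "reduced")
  # indistinguishable from WT -> retained
  expect_equal(classify_variant(wt + 0.001, wt, ctrl)$class, "retained")
  expect_error(classify_variant(c(0.1, 0.2), numeric(), ctrl), "WT")
})

test_that("planted variant truth grids are recovered at >= 95% accuracy", {
  cfg <- synth_config(bret_noise_cv = 0.05, n_wells_per_condition = 3, seed = 17)
  vs <- gen_variant_screen(cfg)
  calls <- variant_call_matrix(vs$plates)
  merged <- merge(calls, vs$grid, by = c("variant", "interactor"),
                  suffixes = c("_called", "_truth"))
  expect_equal(nrow(merged), nrow(vs$grid))
  expect_gte(mean(merged$class_called == merged$class_truth), 0.95)
})

test_that("screen plates analyze end to end through bret_screen", {
  cfg <- synth_config(seed = 29)
  res <- bret_screen(gen_bret_screen(cfg))
  expect_setequal(res$construct_pair, names(cfg$bret_truth))
  expect_true(all(res$sd >= 0))
  positives <- sort(res$construct_pair[res$positive])
  expect_identical(positives, sort(names(which(cfg$bret_truth >= 0.1))))
})
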