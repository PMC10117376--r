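test_that("generation is deterministic under a fixed seed, byte for byte", {
  cfg <- tiny_cfg()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  synth_all(cfg, d1)
  synth_all(cfg, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 9)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("config validation names the offending field", {
  expect_error(synth_config(n_true_interactors = -1), "n_true_interactors")
  expect_error(synth_config(replicate_overlap_fraction = 1.5),
               "replicate_overlap_fraction")
  expect_error(synth_config(planted_clusters = list(c(5, 0))),
               "planted_clusters")
  expect_error(synth_config(bret_truth = c(X = -0.1)), "bret_truth")
})

test_that("AP-MS generator honours its membership contracts", {
  cfg <- tiny_cfg()
  ds <- gen_apms_dataset(cfg)
  t <- ds$truth
  ap1 <- unique(ds$bait$AP1$protein_id)
  ap2 <- unique(ds$bait$AP2$protein_id)
  ctrl <- unique(c(ds$control$CTRL1$protein_id, ds$control$CTRL2$protein_id))
  # full overlap: all true interactors in both baits, never in controls
  expect_true(all(t$true_interactors %in% ap1))
  expect_true(all(t$true_interactors %in% ap2))
  expect_length(intersect(t$true_interactors, ctrl), 0)
  # shared contaminants in bait and control
  expect_true(all(t$contaminant_shared %in% intersect(ap1, ctrl)))
  # per-row peptide counts within the configured range
  for (tab in c(ds$bait, ds$control)) {
    counts <- table(paste(tab$protein_id, tab$experiment))
    expect_true(all(counts >= cfg$peptide_count_range[1]))
    expect_true(all(counts <= cfg$peptide_count_range[2]))
  }
  # observable counts inside the configured range
  expect_true(all(ds$observable_counts$n_observable >= cfg$observable_peptide_range[1]))
  expect_true(all(ds$observable_counts$n_observable <= cfg$observable_peptide_range[2]))
  # a configurable share of peptides below the score threshold, but every
  # detected protein keeps at least one passing peptide
  expect_true(any(ds$bait$AP1$mascot_score < 40))
  hits <- psm_hits(ds$bait$AP1)
  expect_setequal(hits, ap1)
})

test_that("empty-truth config yields bait tables of contaminants only", {
  cfg <- synth_config(n_true_interactors = 0, n_bait_only = c(0, 0),
                      n_contaminant_shared = 3, n_crapome_frequent = 0,
                      n_known_contaminants = 2, seed = 1)
  ds <- gen_apms_dataset(cfg)
  expect_setequal(unique(ds$bait$AP1$protein_id),
                  c(ds$truth$contaminant_shared, ds$truth$known_contaminants))
})

test_that("partial replicate overlap splits the remainder across baits", {
  cfg <- synth_config(n_true_interactors = 20, n_bait_only = c(0, 0),
                      n_contaminant_shared = 0, n_crapome_frequent = 0,
                      n_known_contaminants = 0,
                      replicate_overlap_fraction = 0.5, seed = 9)
  ds <- gen_apms_dataset(cfg)
  ap1 <- unique(ds$bait$AP1$protein_id)
  ap2 <- unique(ds$bait$AP2$protein_id)
  expect_length(intersect(ap1, ap2), 10)
  expect_setequal(union(ap1, ap2), ds$truth$true_interactors)
})

test_that("control-occurrence matrix separates frequent flyers at the >1 boundary", {
  cfg <- tiny_cfg()
  ds <- gen_apms_dataset(cfg)
  occ <- gen_control_occurrence(cfg, ds$truth)
  expect_equal(ncol(occ) - 1L, 30L)
  counts <- occurrence_counts(occ)
  cramed <- counts$protein_id %in% ds$truth$crapome_excluded
  expect_true(all(counts$occurrence[cramed] >= 2))
  expect_true(all(counts$occurrence[!cramed] <= 1))
  # no frequent flyers configured -> all row sums <= 1
  cfg0 <- tiny_cfg(n_crapome_frequent = 0)
  occ0 <- gen_control_occurrence(cfg0)
  expect_true(all(occurrence_counts(occ0)$occurrence <= 1))
})

test_that("string edge generator respects planting, scores and channels", {
  ids <- sprintf("N%02d", 1:20)
  cfg <- tiny_cfg(planted_clusters = list(c(6, 1.0), c(6, 1.0)),
                  background_edge_prob = 0)
  se <- gen_string_edges(ids, cfg)
  expect_true(all(se$edges$combined_score >= 0.70))
  # density 1 plants full cliques
  expect_equal(nrow(se$edges), 2 * choose(6, 2))
  # no clusters, no background -> empty table
  se0 <- gen_string_edges(ids, tiny_cfg(planted_clusters = list(),
                                        background_edge_prob = 0))
  expect_equal(nrow(se0$edges), 0L)
  expect_error(gen_string_edges(ids[1:5], cfg), "exceed")
})

test_that("zero-noise BRET generator inverts exactly through the analysis", {
  cfg <- synth_config(bret_truth = c(CAND = 0.25), bret_noise_cv = 0, seed = 3)
  plate <- gen_bret_screen(cfg)
  ratios <- corrected_ratio(background_correct(plate))
  expect_equal(ratios$ratio[ratios$construct_pair == "CAND"],
               rep(0.25, cfg$n_wells_per_condition), tolerance = 1e-9)
  expect_equal(ratios$ratio[ratios$construct_pair == "Rluc-NLS"],
               rep(0, cfg$n_wells_per_condition), tolerance = 1e-12)
})

test_that("null BRET screen centers corrected ratios on zero", {
  truth <- stats::setNames(rep(0, 6), paste0("C", 1:6))
  cfg <- synth_config(bret_truth = truth, seed = 5)
  plate <- gen_bret_screen(cfg)
  ratios <- corrected_ratio(background_correct(plate))
  experimental <- ratios$ratio[ratios$construct_pair != "Rluc-NLS"]
  se <- sd(experimental) / sqrt(length(experimental))
  expect_lt(abs(mean(experimental)), 3 * se + 1e-3)
})

test_that("gene-set generator realizes the configured overlap structure", {
  cfg <- tiny_cfg(geneset_in_interactome = c(tf = 20, epi = 26, asd = 11,
                                             id = 24, asd_id_overlap = 4,
                                             tf_epi_overlap = 6),
                  geneset_sizes = c(tf = 40, epi = 40, asd = 19, id = 30))
  ids <- sprintf("TI%04d", 1:40)
  gs <- gen_gene_sets(cfg, ids)
  in_asd <- intersect(gs$sets$ASD, ids)
  in_id <- intersect(gs$sets$ID, ids)
  expect_length(in_asd, 11)
  expect_length(in_id, 24)
  expect_length(intersect(in_asd, in_id), 4)
  expect_length(union(in_asd, in_id), 31)
  expect_length(intersect(intersect(gs$sets$TF, ids), intersect(gs$sets$EpiFactors, ids)), 6)
  # disjoint and nested configurations
  cfg0 <- tiny_cfg(geneset_in_interactome = c(tf = 5, epi = 5, asd = 6, id = 9,
                                              asd_id_overlap = 0, tf_epi_overlap = 0))
  gs0 <- gen_gene_sets(cfg0, ids)
  expect_length(union(intersect(gs0$sets$ASD, ids), intersect(gs0$sets$ID, ids)), 15)
  cfgN <- tiny_cfg(geneset_in_interactome = c(tf = 5, epi = 5, asd = 6, id = 9,
                                              asd_id_overlap = 6, tf_epi_overlap = 0))
  gsN <- gen_gene_sets(cfgN, ids)
  expect_length(union(intersect(gsN$sets$ASD, ids), intersect(gsN$sets$ID, ids)), 9)
})
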