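# Synthetic-data generation: every input the pipeline consumes, with
# known ground truth, so all downstream stages are testable offline.
#
# Defaults emulate the published study design: two bait + control AP
# replicates whose hit counts make the replicated set ~43% of AP1 and
# ~68% of AP2 hits, a 30-experiment control-occurrence matrix, planted
# dense clusters in the edge list, a 15-candidate BRET screen with five
# true positives, and a variant-by-interactor truth grid.

#' Synthetic dataset configuration
#'
#' @param n_true_interactors Proteins genuinely bound by the bait
#'   (default 248, the size of the published replicated set).
#' @param n_bait_only Length-2 counts of non-replicated background hits
#'   unique to each AP replicate. Defaults (239, 27) place the replicated
#'   set at ~43% / ~68% of per-replicate hits.
#' @param n_contaminant_shared Proteins detected in bait and control
#'   purifications (default 60).
#' @param n_crapome_frequent Proteins occurring in > 1 of the negative
#'   control experiments (default 25).
#' @param n_known_contaminants Keratin/serum/trypsin entries injected from
#'   the packaged contaminant list (default 5).
#' @param replicate_overlap_fraction Fraction of true interactors present
#'   in both bait replicates (default 1; the remainder alternate).
#' @param peptide_count_range Observed peptides per protein per experiment.
#' @param observable_peptide_range Theoretical observable peptides per
#'   protein.
#' @param below_threshold_fraction Fraction of additional peptides whose
#'   Mascot score falls below 40 (each detected protein always has at
#'   least one passing peptide).
#' @param n_control_experiments Negative-control experiments in the
#'   occurrence matrix (default 30).
#' @param planted_clusters List of `c(size, density)` pairs for dense
#'   clusters planted in the edge list.
#' @param background_edge_prob Probability of a background edge between
#'   any non-cluster pair (default 0.01).
#' @param bret_truth Named non-negative transfer efficiencies per screen
#'   candidate. The default encodes the published 15-candidate screen:
#'   five clear positives, two marginal signals, eight nulls.
#' @param bret_base_ratio Donor-only acceptor/donor ratio (default 0.35,
#'   a typical luciferase bleed-through into the acceptor filter).
#' @param bret_noise_cv Coefficient of variation of well noise
#'   (default 0.05, a realistic plate-reader CV).
#' @param n_wells_per_condition Replicate wells per construct pair
#'   (default 3, assays performed in triplicate).
#' @param n_untransfected_wells Background wells (default 3).
#' @param geneset_in_interactome In-interactome members per gene set:
#'   named counts `tf`, `epi`, `asd`, `id` plus `asd_id_overlap` and
#'   `tf_epi_overlap`. Defaults mirror the published category counts
#'   (26 TFs, 52 epigenetic factors, 11 ASD, 24 ID, 4 shared, 6 dual
#'   TF/epigenetic).
#' @param geneset_sizes Total fixture set sizes (padded with background
#'   symbols), roughly 1/10 the real database scales.
#' @param protein_length Bait protein length for variant logic
#'   (default 682).
#' @param wt_transfer Transfer efficiency of the wild-type bait in
#'   variant assays (default 0.4, the corrected-ratio scale at which
#'   published variant calls separate cleanly at triplicate precision);
#'   reduced calls are planted halfway between abolished and wild type.
#' @param seed Root RNG seed; per-stage stream seeds are derived from it.
#' @return Validated `synth_config` list.
#' @export
synth_config <- function(n_true_interactors = 248L,
                         n_bait_only = c(239L, 27L),
                         n_contaminant_shared = 60L,
                         n_crapome_frequent = 25L,
                         n_known_contaminants = 5L,
                         replicate_overlap_fraction = 1.0,
                         peptide_count_range = c(2L, 8L),
                         observable_peptide_range = c(8L, 30L),
                         below_threshold_fraction = 0.2,
                         n_control_experiments = 30L,
                         planted_clusters = list(c(6, 1.0), c(6, 1.0)),
                         background_edge_prob = 0.01,
                         bret_truth = default_bret_truth(),
                         bret_base_ratio = 0.35,
                         bret_noise_cv = 0.05,
                         n_wells_per_condition = 3L,
                         n_untransfected_wells = 3L,
                         geneset_in_interactome = c(tf = 26L, epi = 52L,
                                                    asd = 11L, id = 24L,
                                                    asd_id_overlap = 4L,
                                                    tf_epi_overlap = 6L),
                         geneset_sizes = c(tf = 150L, epi = 72L,
                                           asd = 19L, id = 75L),
                         protein_length = 682L,
                         wt_transfer = 0.4,
                         seed = 1L) {
  cfg <- list(n_true_interactors = assert_count(n_true_interactors, "n_true_interactors"),
              n_bait_only = c(assert_count(n_bait_only[1], "n_bait_only[1]"),
                              assert_count(n_bait_only[2], "n_bait_only[2]")),
              n_contaminant_shared = assert_count(n_contaminant_shared, "n_contaminant_shared"),
              n_crapome_frequent = assert_count(n_crapome_frequent, "n_crapome_frequent"),
              n_known_contaminants = assert_count(n_known_contaminants, "n_known_contaminants"),
              replicate_overlap_fraction = assert_fraction(replicate_overlap_fraction,
                                                           "replicate_overlap_fraction"),
              peptide_count_range = assert_range(peptide_count_range,
                                                 "peptide_count_range", min = 1L),
              observable_peptide_range = assert_range(observable_peptide_range,
                                                      "observable_peptide_range", min = 1L),
              below_threshold_fraction = assert_fraction(below_threshold_fraction,
                                                         "below_threshold_fraction"),
              n_control_experiments = assert_count(n_control_experiments,
                                                   "n_control_experiments", min = 1L),
              planted_clusters = planted_clusters,
              background_edge_prob = assert_fraction(background_edge_prob,
                                                     "background_edge_prob"),
              bret_truth = bret_truth,
              bret_base_ratio = bret_base_ratio,
              bret_noise_cv = bret_noise_cv,
              n_wells_per_condition = assert_count(n_wells_per_condition,
                                                   "n_wells_per_condition", min = 1L),
              n_untransfected_wells = assert_count(n_untransfected_wells,
                                                   "n_untransfected_wells", min = 1L),
              geneset_in_interactome = geneset_in_interactome,
              geneset_sizes = geneset_sizes,
              protein_length = assert_count(protein_length, "protein_length", min = 1L),
              wt_transfer = wt_transfer,
              seed = assert_count(seed, "seed"))
  for (pc in cfg$planted_clusters) {
    if (length(pc) != 2L || pc[1] < 1 || pc[2] <= 0 || pc[2] > 1) {
      stopf("invalid configuration: 'planted_clusters' entries must be c(size >= 1, density in (0, 1])")
    }
  }
  if (any(cfg$bret_truth < 0)) {
    stopf("invalid configuration: 'bret_truth' transfer efficiencies must be >= 0")
  }
  if (cfg$bret_noise_cv < 0) {
    stopf("invalid configuration: 'bret_noise_cv' must be >= 0")
  }
  structure(cfg, class = "synth_config")
}

#' Default BRET screen truth (published 15-candidate panel shape)
#'
#' Five clear positives, two marginal signals, eight nulls.
#'
#' @return Named numeric vector of transfer efficiencies.
#' @export
default_bret_truth <- function() {
  c(GATAD2B = 0.25, BCOR = 0.22, ADNP = 0.20, NR2F1 = 0.18, NR2F2 = 0.18,
    CTBP2 = 0.02, ZMYM2 = 0.025,
    KDM1A = 0, NCKAP1 = 0, YY1 = 0, CSNK2A1 = 0, SMARCA2 = 0,
    TBL1XR1 = 0, CTNND1 = 0, CTBP1 = 0)
}

random_peptide <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(8:15, 1), replace = TRUE), collapse = "")
  }, character(1))
}

# Per-protein PSM block for one experiment: scores are gamma-shifted above
# the threshold, except a configured fraction of extra peptides below 40.
# The first peptide always passes, so detection survives score filtering.
psm_block <- function(protein, experiment, condition, cfg, peptide_pool) {
  n_pep <- sample(seq(cfg$peptide_count_range[1], cfg$peptide_count_range[2]), 1)
  peps <- sample(peptide_pool[[protein]], n_pep)
  low <- c(FALSE, stats::runif(n_pep - 1) < cfg$below_threshold_fraction)
  score <- ifelse(low,
                  stats::runif(n_pep, 10, 39.9),
                  40 + stats::rgamma(n_pep, shape = 2, scale = 15))
  data.frame(protein_id = protein, peptide_seq = peps,
             mascot_score = round(score, 2),
             experiment = experiment, condition = condition,
             stringsAsFactors = FALSE)
}

synth_protein_ids <- function(cfg) {
  known <- default_contaminants()
  if (cfg$n_known_contaminants > length(known)) {
    stopf("invalid configuration: 'n_known_contaminants' exceeds the packaged contaminant list (%d)",
          length(known))
  }
  list(true_interactors = sprintf("TI%04d", seq_len(cfg$n_true_interactors)),
       bait_only_1 = sprintf("B1X%04d", seq_len(cfg$n_bait_only[1])),
       bait_only_2 = sprintf("B2X%04d", seq_len(cfg$n_bait_only[2])),
       contaminant_shared = sprintf("CS%04d", seq_len(cfg$n_contaminant_shared)),
       crapome_frequent = sprintf("CR%04d", seq_len(cfg$n_crapome_frequent)),
       known_contaminants = known[seq_len(cfg$n_known_contaminants)])
}

#' Generate a two-replicate AP-MS dataset with ground truth
#'
#' True interactors appear in bait purifications only (both replicates
#' for a `replicate_overlap_fraction` of them, alternating single
#' replicates for the rest); contaminant-shared proteins appear in bait
#' and control; CRAPome-frequent proteins appear in both baits but are
#' flagged for occurrence-based exclusion; packaged known contaminants
#' appear everywhere.
#'
#' @param cfg A [synth_config()].
#' @return List with `bait` (named list of 2 PSM tables), `control`
#'   (2 PSM tables), `observable_counts` (data frame), and `truth` (list
#'   of id sets: `true_interactors`, `in_both_replicates`,
#'   `contaminant_shared`, `crapome_excluded`, `known_contaminants`,
#'   `bait_only`).
#' @export
gen_apms_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  ids <- synth_protein_ids(cfg)
  withr::with_seed(stream_seed(cfg$seed, "apms"), {
    n_both <- round(cfg$replicate_overlap_fraction * cfg$n_true_interactors)
    both <- ids$true_interactors[seq_len(n_both)]
    rest <- setdiff(ids$true_interactors, both)
    rest_ap1 <- rest[seq_along(rest) %% 2L == 1L]
    rest_ap2 <- setdiff(rest, rest_ap1)

    membership <- list(
      AP1 = c(both, rest_ap1, ids$bait_only_1, ids$contaminant_shared,
              ids$crapome_frequent, ids$known_contaminants),
      AP2 = c(both, rest_ap2, ids$bait_only_2, ids$contaminant_shared,
              ids$crapome_frequent, ids$known_contaminants),
      CTRL1 = c(ids$contaminant_shared, ids$known_contaminants),
      CTRL2 = c(ids$contaminant_shared, ids$known_contaminants))

    all_proteins <- sort(unique(unlist(membership)))
    peptide_pool <- lapply(stats::setNames(all_proteins, all_proteins), function(p) {
      random_peptide(cfg$peptide_count_range[2])
    })
    observable <- data.frame(
      protein_id = all_proteins,
      n_observable = sample(seq(cfg$observable_peptide_range[1],
                                cfg$observable_peptide_range[2]),
                            length(all_proteins), replace = TRUE),
      stringsAsFactors = FALSE)

    make_table <- function(proteins, experiment, condition) {
      if (length(proteins) == 0L) {
        return(data.frame(protein_id = character(), peptide_seq = character(),
                          mascot_score = numeric(), experiment = character(),
                          condition = character(), stringsAsFactors = FALSE))
      }
      do.call(rbind, lapply(sort(proteins), psm_block, experiment = experiment,
                            condition = condition, cfg = cfg,
                            peptide_pool = peptide_pool))
    }
    bait <- list(AP1 = make_table(membership$AP1, "AP1", "bait"),
                 AP2 = make_table(membership$AP2, "AP2", "bait"))
    control <- list(CTRL1 = make_table(membership$CTRL1, "AP1", "control"),
                    CTRL2 = make_table(membership$CTRL2, "AP2", "control"))
    list(bait = bait, control = control, observable_counts = observable,
         truth = list(true_interactors = ids$true_interactors,
                      in_both_replicates = both,
                      contaminant_shared = ids$contaminant_shared,
                      crapome_excluded = ids$crapome_frequent,
                      known_contaminants = ids$known_contaminants,
                      bait_only = list(AP1 = ids$bait_only_1,
                                       AP2 = ids$bait_only_2)))
  })
}

#' Generate a binary control-occurrence matrix
#'
#' Proteins flagged as CRAPome-excluded in the ground truth occur in 2 or
#' more of the control experiments; every other protein occurs in at most
#' 1.
#'
#' @param cfg A [synth_config()].
#' @param truth Ground-truth list from [gen_apms_dataset()]; regenerated
#'   from `cfg` when omitted.
#' @return Data frame: `protein_id` plus `n_control_experiments` binary
#'   columns `ctrl01`...
#' @export
gen_control_occurrence <- function(cfg = synth_config(), truth = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(truth)) truth <- gen_apms_dataset(cfg)$truth
  withr::with_seed(stream_seed(cfg$seed, "crapome"), {
    proteins <- sort(unique(c(truth$true_interactors, truth$contaminant_shared,
                              truth$crapome_excluded, truth$known_contaminants,
                              unlist(truth$bait_only))))
    ncols <- cfg$n_control_experiments
    frequent <- proteins %in% truth$crapome_excluded
    if (any(frequent) && ncols < 2L) {
      stopf("cannot plant CRAPome-frequent proteins with fewer than 2 control experiments")
    }
    mat <- matrix(0L, nrow = length(proteins), ncol = ncols,
                  dimnames = list(proteins, sprintf("ctrl%02d", seq_len(ncols))))
    for (i in seq_along(proteins)) {
      occ <- if (frequent[i]) sample(2:min(5, ncols), 1) else sample(0:1, 1)
      if (occ > 0) mat[i, sample(ncols, occ)] <- 1L
    }
    cbind(data.frame(protein_id = proteins, stringsAsFactors = FALSE),
          as.data.frame(mat))
  })
}

#' Generate a confidence-scored edge list with planted dense clusters
#'
#' Planted clusters receive within-cluster edges with the configured
#' density, scores in `[0.70, 1.0)` and experimental/database evidence so
#' they survive the default graph filter; background edges are sparse
#' with scores in `[0.15, 1.0)` and arbitrary evidence channels.
#'
#' @param protein_ids Proteins to draw edges over.
#' @param cfg A [synth_config()].
#' @return List with `edges` (data frame `protein_a`, `protein_b`,
#'   `combined_score`, `channels`) and `cluster_membership` (named
#'   cluster id per planted protein).
#' @export
gen_string_edges <- function(protein_ids, cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  protein_ids <- sort(unique(canonical_symbol(protein_ids)))
  total_planted <- sum(vapply(cfg$planted_clusters, `[`, numeric(1), 1))
  if (total_planted > length(protein_ids)) {
    stopf("planted cluster sizes (%d) exceed the number of proteins (%d)",
          total_planted, length(protein_ids))
  }
  withr::with_seed(stream_seed(cfg$seed, "string"), {
    membership <- integer(0)
    edges <- list()
    offset <- 0L
    for (ci in seq_along(cfg$planted_clusters)) {
      size <- as.integer(cfg$planted_clusters[[ci]][1])
      density <- cfg$planted_clusters[[ci]][2]
      members <- protein_ids[offset + seq_len(size)]
      offset <- offset + size
      membership[members] <- ci
      if (size >= 2L) {
        pairs <- utils::combn(members, 2)
        keep <- stats::runif(ncol(pairs)) <= density
        if (any(keep)) {
          edges[[length(edges) + 1L]] <- data.frame(
            protein_a = pairs[1, keep], protein_b = pairs[2, keep],
            combined_score = round(stats::runif(sum(keep), 0.70, 0.9999), 3),
            channels = sample(c("experimental", "database",
                                "experimental;database"),
                              sum(keep), replace = TRUE),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (cfg$background_edge_prob > 0 && length(protein_ids) >= 2L) {
      planted <- names(membership)
      pairs <- utils::combn(protein_ids, 2)
      same_cluster <- pairs[1, ] %in% planted & pairs[2, ] %in% planted &
        membership[pairs[1, ]] == membership[pairs[2, ]]
      candidate <- which(!same_cluster)
      keep <- candidate[stats::runif(length(candidate)) <= cfg$background_edge_prob]
      if (length(keep) > 0L) {
        edges[[length(edges) + 1L]] <- data.frame(
          protein_a = pairs[1, keep], protein_b = pairs[2, keep],
          combined_score = round(stats::runif(length(keep), 0.15, 0.9999), 3),
          channels = sample(c("experimental", "database", "textmining",
                              "textmining;coexpression"),
                            length(keep), replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    edges <- if (length(edges) > 0L) do.call(rbind, edges) else
      data.frame(protein_a = character(), protein_b = character(),
                 combined_score = numeric(), channels = character(),
                 stringsAsFactors = FALSE)
    rownames(edges) <- NULL
    list(edges = edges, cluster_membership = membership)
  })
}

#' Generate an interaction graph with a fixed component layout
#'
#' Builds an edge list realizing a prescribed component-size profile and
#' total edge count over `n_nodes` proteins: each listed component gets a
#' random spanning tree, and the remaining edge budget is spent on extra
#' random edges inside the largest component. All scores are >= 0.70 with
#' experimental evidence, so the default graph filter keeps everything.
#' Nodes outside the listed components stay isolated.
#'
#' @param n_nodes Total proteins (default 248).
#' @param component_sizes Sizes of the non-singleton components
#'   (default: one 154-protein component, two trios, five pairs).
#' @param n_edges Total edge count (default 604).
#' @param seed RNG seed.
#' @return List with `nodes` and `edges`.
#' @export
gen_component_layout <- function(n_nodes = 248L,
                                 component_sizes = c(154L, 3L, 3L, 2L, 2L, 2L, 2L, 2L),
                                 n_edges = 604L, seed = 1L) {
  if (sum(component_sizes) > n_nodes) {
    stopf("component sizes exceed the node count")
  }
  min_edges <- sum(component_sizes - 1L)
  if (n_edges < min_edges) {
    stopf("n_edges (%d) below the minimum spanning requirement (%d)",
          n_edges, min_edges)
  }
  nodes <- sprintf("P%04d", seq_len(n_nodes))
  withr::with_seed(stream_seed(seed, "layout"), {
    edges <- list()
    offset <- 0L
    comp_members <- list()
    for (size in component_sizes) {
      members <- nodes[offset + seq_len(size)]
      offset <- offset + size
      comp_members[[length(comp_members) + 1L]] <- members
      if (size >= 2L) {
        # random spanning tree: attach each node to a random predecessor
        for (i in 2:size) {
          edges[[length(edges) + 1L]] <- c(members[sample(i - 1L, 1)], members[i])
        }
      }
    }
    extra <- n_edges - min_edges
    big <- comp_members[[which.max(component_sizes)]]
    pairs <- utils::combn(big, 2)
    have <- vapply(edges, function(e) paste(sort(e), collapse = "\r"), character(1))
    pool_keys <- paste(pmin(pairs[1, ], pairs[2, ]), pmax(pairs[1, ], pairs[2, ]), sep = "\r")
    avail <- which(!pool_keys %in% have)
    if (extra > length(avail)) {
      stopf("edge budget exceeds the capacity of the largest component")
    }
    pick <- sample(avail, extra)
    for (i in pick) edges[[length(edges) + 1L]] <- c(pairs[1, i], pairs[2, i])
    el <- do.call(rbind, edges)
    list(nodes = nodes,
         edges = data.frame(protein_a = el[, 1], protein_b = el[, 2],
                            combined_score = round(stats::runif(nrow(el), 0.70, 0.9999), 3),
                            channels = "experimental",
                            stringsAsFactors = FALSE))
  })
}

synth_plate <- function(pairs, transfer, cfg, control_label,
                        n_wells, n_untransfected,
                        bg_blue = 200, bg_green = 100,
                        blue_meanlog = log(5e4), blue_sdlog = 0.15) {
  rows <- list()
  well_i <- 0L
  add_wells <- function(label, condition, eff) {
    for (w in seq_len(n_wells)) {
      well_i <<- well_i + 1L
      blue_true <- stats::rlnorm(1, blue_meanlog, blue_sdlog)
      noise <- 1 + cfg$bret_noise_cv * stats::rnorm(1)
      green_true <- blue_true * (cfg$bret_base_ratio + eff) * noise
      rows[[length(rows) + 1L]] <<- data.frame(
        well = sprintf("W%03d", well_i), condition = condition,
        construct_pair = label, Blue1 = bg_blue + blue_true,
        Green1 = bg_green + green_true, stringsAsFactors = FALSE)
    }
  }
  for (w in seq_len(n_untransfected)) {
    well_i <- well_i + 1L
    noise_b <- 1 + cfg$bret_noise_cv * stats::rnorm(1)
    noise_g <- 1 + cfg$bret_noise_cv * stats::rnorm(1)
    rows[[length(rows) + 1L]] <- data.frame(
      well = sprintf("W%03d", well_i), condition = "untransfected",
      construct_pair = "none", Blue1 = bg_blue * noise_b,
      Green1 = bg_green * noise_g, stringsAsFactors = FALSE)
  }
  add_wells(control_label, "donor_only_control", 0)
  for (p in pairs) add_wells(p, "experimental", transfer[[p]])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a BRET screening plate
#'
#' Donor (`Blue1`) counts are lognormal; acceptor (`Green1`) counts equal
#' the donor signal times `base_ratio + transfer_efficiency` with
#' multiplicative noise; constant instrument background is added to every
#' well and emitted as untransfected wells (so zero-noise plates invert
#' exactly through [background_correct()] and [corrected_ratio()]).
#'
#' @param cfg A [synth_config()]; `bret_truth` supplies candidate names
#'   and transfer efficiencies.
#' @param control_label Donor-only control label (default "Rluc-NLS").
#' @return Plate data frame (see [read_plate()]).
#' @export
gen_bret_screen <- function(cfg = synth_config(), control_label = "Rluc-NLS") {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(stream_seed(cfg$seed, "bret"), {
    synth_plate(names(cfg$bret_truth), cfg$bret_truth, cfg, control_label,
                cfg$n_wells_per_condition, cfg$n_untransfected_wells)
  })
}

#' Generate variant-assay plates from a planted truth grid
#'
#' One plate per interactor, carrying the control fusion, the wild-type
#' bait, and every variant. Planted classes map to transfer efficiencies:
#' retained = `wt_transfer`, reduced = half of it, abolished = 0.
#'
#' @param cfg A [synth_config()].
#' @param grid Data frame `variant`, `interactor`, `class`; defaults to
#'   the packaged published call grid.
#' @param wt_label,control_label Group labels (defaults "WT", "YFP-NLS").
#' @return List with `plates` (named list of plate data frames) and
#'   `grid` (the truth grid used).
#' @export
gen_variant_screen <- function(cfg = synth_config(), grid = default_call_grid(),
                               wt_label = "WT", control_label = "YFP-NLS") {
  stopifnot(inherits(cfg, "synth_config"))
  eff <- c(retained = cfg$wt_transfer, reduced = 0.5 * cfg$wt_transfer,
           abolished = 0)
  withr::with_seed(stream_seed(cfg$seed, "variants"), {
    plates <- list()
    for (interactor in sort(unique(grid$interactor))) {
      sub <- grid[grid$interactor == interactor, , drop = FALSE]
      transfer <- c(stats::setNames(unname(eff[sub$class]), sub$variant),
                    stats::setNames(cfg$wt_transfer, wt_label))
      pairs <- c(wt_label, sub$variant)
      plates[[interactor]] <- synth_plate(pairs, transfer, cfg, control_label,
                                          cfg$n_wells_per_condition,
                                          cfg$n_untransfected_wells)
    }
    list(plates = plates, grid = grid)
  })
}

#' Generate annotation gene sets with configured interactome overlap
#'
#' Builds TF, epigenetic-factor, ASD and ID sets whose in-interactome
#' member counts (and the ASD/ID and TF/epigenetic overlaps) are fixed by
#' the configuration, padded to the fixture set sizes with background
#' symbols.
#'
#' @param cfg A [synth_config()].
#' @param interactome_ids Proteins of the interactome to sample members
#'   from.
#' @return A `gene_set_collection` with sets `TF`, `EpiFactors`, `ASD`,
#'   `ID`.
#' @export
gen_gene_sets <- function(cfg = synth_config(), interactome_ids) {
  stopifnot(inherits(cfg, "synth_config"))
  g <- cfg$geneset_in_interactome
  interactome_ids <- sort(unique(canonical_symbol(interactome_ids)))
  need <- max(g[["tf"]] + g[["epi"]] - g[["tf_epi_overlap"]],
              g[["asd"]] + g[["id"]] - g[["asd_id_overlap"]])
  if (need > length(interactome_ids)) {
    stopf("interactome too small (%d) for the configured in-set counts (%d)",
          length(interactome_ids), need)
  }
  withr::with_seed(stream_seed(cfg$seed, "genesets"), {
    pick <- function(pool, n) if (n > 0) sample(pool, n) else character()
    # TF/epigenetic block
    tf_epi_union <- pick(interactome_ids, g[["tf"]] + g[["epi"]] - g[["tf_epi_overlap"]])
    dual <- tf_epi_union[seq_len(g[["tf_epi_overlap"]])]
    tf_in <- c(dual, setdiff(tf_epi_union, dual)[seq_len(g[["tf"]] - g[["tf_epi_overlap"]])])
    epi_in <- c(dual, setdiff(tf_epi_union, tf_in))
    # ASD/ID block
    asd_id_union <- pick(interactome_ids, g[["asd"]] + g[["id"]] - g[["asd_id_overlap"]])
    shared <- asd_id_union[seq_len(g[["asd_id_overlap"]])]
    asd_in <- c(shared, setdiff(asd_id_union, shared)[seq_len(g[["asd"]] - g[["asd_id_overlap"]])])
    id_in <- c(shared, setdiff(asd_id_union, asd_in))

    pad <- function(members, total, prefix) {
      extra <- max(0L, total - length(members))
      sort(c(members, sprintf("%s%04d", prefix, seq_len(extra))))
    }
    sets <- list(TF = pad(tf_in, cfg$geneset_sizes[["tf"]], "BGTF"),
                 EpiFactors = pad(epi_in, cfg$geneset_sizes[["epi"]], "BGEP"),
                 ASD = pad(asd_in, cfg$geneset_sizes[["asd"]], "BGAS"),
                 ID = pad(id_in, cfg$geneset_sizes[["id"]], "BGID"))
    structure(list(sets = sets,
                   provenance = c(TF = "synthetic TF fixture",
                                  EpiFactors = "synthetic epigenetic-factor fixture",
                                  ASD = "synthetic ASD fixture",
                                  ID = "synthetic ID fixture")),
              class = "gene_set_collection")
  })
}

#' Write every synthetic input to a directory
#'
#' Emits the PSM TSVs, observable-count TSV, control-occurrence TSV, edge
#' TSV, gene-set GMT, BRET plate CSV and truth JSON. Identical
#' configurations (including seed) produce byte-identical files.
#'
#' @param cfg A [synth_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of paths written.
#' @export
synth_all <- function(cfg = synth_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- gen_apms_dataset(cfg)
  occ <- gen_control_occurrence(cfg, ds$truth)
  se <- gen_string_edges(ds$truth$true_interactors, cfg)
  gs <- gen_gene_sets(cfg, ds$truth$true_interactors)
  plate <- gen_bret_screen(cfg)
  paths <- c(
    write_tsv(ds$bait$AP1, file.path(outdir, "ap1_bait.tsv")),
    write_tsv(ds$bait$AP2, file.path(outdir, "ap2_bait.tsv")),
    write_tsv(ds$control$CTRL1, file.path(outdir, "ap1_control.tsv")),
    write_tsv(ds$control$CTRL2, file.path(outdir, "ap2_control.tsv")),
    write_tsv(ds$observable_counts, file.path(outdir, "observable_counts.tsv")),
    write_tsv(occ, file.path(outdir, "crapome_occurrence.tsv")),
    write_tsv(se$edges, file.path(outdir, "string_edges.tsv")),
    write_gmt(gs, file.path(outdir, "gene_sets.gmt")),
    write_csv(plate, file.path(outdir, "bret_plate.csv")))
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(ds$truth, truth_path, auto_unbox = FALSE, pretty = TRUE)
  invisible(c(paths, truth_path))
}
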