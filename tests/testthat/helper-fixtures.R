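# Shared small fixtures built in code.

tiny_cfg <- function(...) {
  defaults <- list(n_true_interactors = 40, n_bait_only = c(12, 6),
                   n_contaminant_shared = 8, n_crapome_frequent = 5,
                   n_known_contaminants = 5, seed = 42,
                   geneset_in_interactome = c(tf = 8, epi = 12, asd = 5,
                                              id = 9, asd_id_overlap = 2,
                                              tf_epi_overlap = 3),
                   geneset_sizes = c(tf = 20, epi = 25, asd = 10, id = 15))
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# edge data frame from a plain vector of "A-B" strings, all passing the
# default score/channel filter
edge_df <- function(pairs, score = 0.9, channels = "experimental") {
  if (length(pairs) == 0) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      combined_score = numeric(), channels = character(),
                      stringsAsFactors = FALSE))
  }
  sp <- strsplit(pairs, "-", fixed = TRUE)
  data.frame(protein_a = vapply(sp, `[`, character(1), 1),
             protein_b = vapply(sp, `[`, character(1), 2),
             combined_score = score, channels = channels,
             stringsAsFactors = FALSE)
}

clique_pairs <- function(members) {
  cmb <- utils::combn(members, 2)
  paste(cmb[1, ], cmb[2, ], sep = "-")
}

path_pairs <- function(members) {
  paste(members[-length(members)], members[-1], sep = "-")
}

# deterministic plate built directly (no generator): one row per well
manual_plate <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(well = r[[1]], condition = r[[2]], construct_pair = r[[3]],
               Blue1 = as.numeric(r[[4]]), Green1 = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)
  }))
}
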