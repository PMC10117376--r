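# Gene-set annotation of the interactome and candidate prioritization.

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then members (tab-separated).
#' Duplicate members within a line are stored once; symbols are
#' canonicalized (uppercase, whitespace-stripped).
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: list with `sets` (named list of symbol
#'   vectors) and `provenance` (named character of descriptions).
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  prov <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stopf("malformed GMT line %d in %s: expected name, description and >= 1 member", i, path)
    }
    nm <- parts[1]
    sets[[nm]] <- unique(canonical_symbol(parts[-(1:2)]))
    prov[nm] <- parts[2]
  }
  structure(list(sets = sets, provenance = prov), class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection` (or bare named list of sets).
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets else collection
  prov <- if (inherits(collection, "gene_set_collection")) collection$provenance else NULL
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(prov) && nm %in% names(prov)) prov[[nm]] else "synthetic"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Annotate proteins with gene-set membership and count categories
#'
#' Flags every protein for membership in every set and reports per-set
#' counts with half-up integer percentages (`floor(100k/n + 0.5)`), the
#' rounding used in published category tables. When both an ASD and an ID
#' set are identified (via `roles`), a derived `ASD_or_ID` flag/count is
#' added.
#'
#' @param proteins Character vector of protein symbols.
#' @param sets A `gene_set_collection` or named list of symbol vectors.
#' @param roles Optional named character mapping roles `asd` and `id` to
#'   set names, e.g. `c(asd = "ASD", id = "ID")`. Defaults to set names
#'   matching (case-insensitively) "ASD" and "ID" when present.
#' @return List with `table` (data frame of logical flags per set) and
#'   `counts` (data frame `set`, `count`, `percent`).
#' @export
annotate_and_count <- function(proteins, sets, roles = NULL) {
  setlist <- if (inherits(sets, "gene_set_collection")) sets$sets else sets
  setlist <- lapply(setlist, canonical_symbol)
  proteins <- canonical_symbol(unique(proteins))
  n <- length(proteins)
  if (n == 0L) warnf("empty protein list: counts are 0 and percentages reported as 0")

  tab <- data.frame(protein_id = proteins, stringsAsFactors = FALSE)
  for (nm in names(setlist)) tab[[nm]] <- proteins %in% setlist[[nm]]

  if (is.null(roles)) {
    roles <- c()
    ln <- tolower(names(setlist))
    if ("asd" %in% ln) roles["asd"] <- names(setlist)[match("asd", ln)]
    if ("id" %in% ln) roles["id"] <- names(setlist)[match("id", ln)]
  }
  if (all(c("asd", "id") %in% names(roles))) {
    tab$ASD_or_ID <- tab[[roles[["asd"]]]] | tab[[roles[["id"]]]]
  }

  count_cols <- setdiff(names(tab), "protein_id")
  counts <- data.frame(
    set = count_cols,
    count = vapply(count_cols, function(cn) sum(tab[[cn]]), integer(1)),
    stringsAsFactors = FALSE)
  counts$percent <- if (n > 0) percent_int(counts$count, n) else 0L
  rownames(counts) <- NULL
  list(table = tab, counts = counts)
}

#' Overlap between two gene sets
#'
#' @param set_a,set_b Character vectors of symbols.
#' @return List with `n_a`, `n_b`, `n_intersect`, `n_union`, `shared`
#'   (sorted shared members). The inclusion-exclusion identity
#'   `n_union = n_a + n_b - n_intersect` holds by construction.
#' @export
overlap_summary <- function(set_a, set_b) {
  a <- unique(canonical_symbol(set_a))
  b <- unique(canonical_symbol(set_b))
  shared <- sort(intersect(a, b))
  list(n_a = length(a), n_b = length(b),
       n_intersect = length(shared),
       n_union = length(union(a, b)),
       shared = shared)
}

#' Single-cell expression filter
#'
#' Retains proteins detected at or above `min_tpm` transcripts per million
#' in the reference cell type. Proteins missing from the expression table
#' are treated as 0 TPM (and counted in a message).
#'
#' @param proteins Character vector of symbols.
#' @param tpm_table Data frame (`protein_id`, `tpm`) or named numeric.
#' @param min_tpm Detection threshold, default 1 TPM (inclusive).
#' @return List with `detected` (sorted symbols), `n`, `n_total`, and
#'   `percent` (half-up integer).
#' @export
expression_filter <- function(proteins, tpm_table, min_tpm = 1.0) {
  proteins <- unique(canonical_symbol(proteins))
  tpm <- if (is.data.frame(tpm_table)) {
    stats::setNames(tpm_table$tpm, canonical_symbol(tpm_table$protein_id))
  } else {
    stats::setNames(as.numeric(tpm_table), canonical_symbol(names(tpm_table)))
  }
  vals <- tpm[proteins]
  n_missing <- sum(is.na(vals))
  if (n_missing > 0L) {
    message(sprintf("%d protein(s) missing from the expression table; treated as 0 TPM",
                    n_missing))
  }
  vals[is.na(vals)] <- 0
  detected <- sort(proteins[vals >= min_tpm])
  list(detected = detected, n = length(detected), n_total = length(proteins),
       percent = if (length(proteins) > 0) percent_int(length(detected), length(proteins)) else 0L)
}

#' Rank and assemble validation candidates
#'
#' Builds the candidate list for independent validation in three stages:
#' (1) interactome proteins annotated to the NDD (ASD-or-ID) set, ranked
#' by mean emPAI descending (ties broken lexicographically), keeping the
#' top `top_n`; (2) members of `shared_interactors` (proteins known to
#' bind established partner TFs of the bait) present in the interactome
#' and not already selected; (3) paralogs of stage-2 picks from
#' `paralog_map`, appended regardless of whether they replicated in the
#' interactome. Duplicates keep their first source tag.
#'
#' @param interactome Character vector, the filtered interactome.
#' @param ndd_set Character vector of NDD-annotated symbols, or an
#'   annotation table from [annotate_and_count()] (its `ASD_or_ID` flag is
#'   used).
#' @param abundance Abundance table from [protein_abundance()].
#' @param top_n Number of emPAI-ranked NDD candidates (default 10).
#' @param shared_interactors Stage-2 candidate symbols.
#' @param paralog_map Named character: names are stage-2 picks, values
#'   their paralogs.
#' @return Data frame `candidate`, `source`
#'   (`top_empai_ndd`/`shared_interactor`/`paralog_augment`),
#'   `mean_empai` (NA when not quantified).
#' @export
prioritize_candidates <- function(interactome, ndd_set, abundance,
                                  top_n = 10L,
                                  shared_interactors = character(),
                                  paralog_map = character()) {
  interactome <- unique(canonical_symbol(interactome))
  if (is.data.frame(ndd_set)) {
    if (!"ASD_or_ID" %in% names(ndd_set)) {
      stopf("annotation table lacks an 'ASD_or_ID' column")
    }
    ndd_set <- ndd_set$protein_id[ndd_set$ASD_or_ID]
  }
  ndd_set <- canonical_symbol(ndd_set)
  empai <- stats::setNames(abundance$mean_empai, canonical_symbol(abundance$protein_id))

  pool <- sort(intersect(interactome, ndd_set))
  if (any(!pool %in% names(empai))) {
    stopf("abundance table does not cover: %s",
          paste(setdiff(pool, names(empai)), collapse = ", "))
  }
  if (top_n > length(pool)) {
    warnf("top_n (%d) exceeds the NDD pool size (%d); returning the whole pool",
          top_n, length(pool))
    top_n <- length(pool)
  }
  ranked <- pool[order(-empai[pool], pool)]
  stage1 <- ranked[seq_len(top_n)]

  stage2 <- sort(setdiff(intersect(canonical_symbol(shared_interactors), interactome),
                         stage1))
  paralog_map <- stats::setNames(canonical_symbol(paralog_map),
                                 canonical_symbol(names(paralog_map)))
  stage3 <- unname(paralog_map[names(paralog_map) %in% stage2])
  stage3 <- sort(setdiff(stage3, c(stage1, stage2)))

  out <- data.frame(
    candidate = c(stage1, stage2, stage3),
    source = c(rep("top_empai_ndd", length(stage1)),
               rep("shared_interactor", length(stage2)),
               rep("paralog_augment", length(stage3))),
    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$candidate), , drop = FALSE]
  out$mean_empai <- unname(empai[out$candidate])
  rownames(out) <- NULL
  out
}
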