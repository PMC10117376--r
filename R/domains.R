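# Binding-region inference from variant panels and interaction-call
# matrices: which residue intervals of the bait protein are required for,
# or involved in, each validated interaction.

#' Parse protein-level variant nomenclature
#'
#' Supports missense (`p.K228E`), nonsense (`p.N394*`) and frameshift
#' (`p.A136Pfs*80`) descriptions.
#'
#' @param variant_id Variant string.
#' @return List `kind` (missense/nonsense/frameshift), `position`,
#'   and for frameshifts `tail_length`.
#' @export
parse_variant <- function(variant_id) {
  v <- trimws(variant_id)
  m <- regmatches(v, regexec("^p\\.([A-Z])([0-9]+)([A-Z][a-z]*)?fs\\*?([0-9]+)?$", v))[[1]]
  if (length(m) > 0) {
    return(list(kind = "frameshift", position = as.integer(m[3]),
                tail_length = if (nzchar(m[5])) as.integer(m[5]) else NA_integer_))
  }
  m <- regmatches(v, regexec("^p\\.([A-Z])([0-9]+)\\*$", v))[[1]]
  if (length(m) > 0) {
    return(list(kind = "nonsense", position = as.integer(m[3])))
  }
  m <- regmatches(v, regexec("^p\\.([A-Z])([0-9]+)([A-Z])$", v))[[1]]
  if (length(m) > 0) {
    return(list(kind = "missense", position = as.integer(m[3])))
  }
  stopf("cannot parse variant nomenclature '%s'", variant_id)
}

#' Intact residue interval of a variant protein
#'
#' Truncating variants `p.X*` leave residues `[1, X-1]` intact; frameshift
#' variants `p.Xfs*N` likewise keep `[1, X-1]` (the aberrant tail is
#' ignored for interval logic, and flagged); missense variants keep the
#' full length with a point annotation.
#'
#' @param variant_id Variant string (see [parse_variant()]).
#' @param protein_length Full protein length in residues.
#' @return List `interval` (`c(start, end)`), `kind`, `position`,
#'   `frameshift_tail_ignored` flag.
#' @export
variant_intact_interval <- function(variant_id, protein_length) {
  p <- parse_variant(variant_id)
  if (p$position > protein_length) {
    stopf("variant position %d exceeds protein length %d for '%s'",
          p$position, protein_length, variant_id)
  }
  if (p$kind == "missense") {
    list(interval = c(1L, as.integer(protein_length)), kind = p$kind,
         position = p$position, frameshift_tail_ignored = FALSE)
  } else {
    list(interval = c(1L, p$position - 1L), kind = p$kind,
         position = p$position,
         frameshift_tail_ignored = p$kind == "frameshift")
  }
}

#' Packaged bait-protein variant panel
#'
#' The eleven patient variants plus two synthetic truncations used for
#' binding-site mapping, with provenance labels.
#'
#' @return Data frame `variant`, `kind`, `position`, `provenance`.
#' @export
default_variant_panel <- function() {
  read_tsv(system.file("extdata", "tbr1_variants.tsv", package = "ppikit"))
}

#' Packaged published interaction-call grid (fixture transcription)
#'
#' Variant-by-interactor calls for the five validated interactors,
#' transcribed from the published variant figures.
#'
#' @return Data frame `variant`, `interactor`, `class`.
#' @export
default_call_grid <- function() {
  read_tsv(system.file("extdata", "tbr1_call_grid.tsv", package = "ppikit"))
}

#' Default named protein regions
#'
#' T-box DNA-binding domain (residues 213-393) and C-terminal region
#' (residues 394-567, one residue before the distal synthetic truncation
#' point).
#'
#' @param protein_length Protein length (default 682).
#' @return Data frame `region`, `start`, `end`.
#' @export
default_regions <- function(protein_length = 682L) {
  data.frame(region = c("T-box", "C-terminal"),
             start = c(213L, 394L), end = c(393L, 567L),
             stringsAsFactors = FALSE)
}

intact_end <- function(variant, variants_df, protein_length) {
  row <- variants_df[variants_df$variant == variant, , drop = FALSE]
  if (nrow(row) == 0L) stopf("variant '%s' not in the panel", variant)
  variant_intact_interval(variant, protein_length)$interval[2]
}

regions_overlapping <- function(interval, regions) {
  if (is.null(interval)) return(character())
  hit <- regions$start <= interval[2] & regions$end >= interval[1]
  regions$region[hit]
}

intersect_intervals <- function(ivs) {
  lo <- max(vapply(ivs, `[`, numeric(1), 1))
  hi <- min(vapply(ivs, `[`, numeric(1), 2))
  if (lo > hi) NULL else c(lo, hi)
}

#' Infer required and involved binding regions per interactor
#'
#' Truncation logic: for every pair of truncating variants (R retaining
#' the interaction, L losing it) with the intact prefix of L strictly
#' inside that of R, the residues present in R but not L must contain the
#' binding determinant; intervals from multiple pairs are intersected.
#' "Reduced" calls count as retaining for this set logic, but a reduced
#' truncation paired against a longer fully-retained truncation
#' additionally contributes its differential interval as *involved*
#' (partial) evidence. Missense losses never bound an interval; they mark
#' their containing named region as involved. Regions wholly absent from
#' a retained truncation are reported as dispensable.
#'
#' @param calls Data frame `variant`, `interactor`, `class`
#'   (retained/reduced/abolished).
#' @param variants Variant panel data frame (`variant`, `kind`, ...).
#' @param regions Named region table (default [default_regions()]).
#' @param protein_length Bait protein length (default 682).
#' @return Named list per interactor: `required_interval`,
#'   `required_regions`, `involved_regions`, `dispensable_regions`,
#'   `supporting_variants`, `missense_losses`, `n_truncation_pairs`.
#'   Interactors with no truncation data yield involvement-only inference
#'   with a warning.
#' @export
infer_required_regions <- function(calls, variants,
                                   regions = default_regions(),
                                   protein_length = 682L) {
  stopifnot(all(c("variant", "interactor", "class") %in% names(calls)))
  out <- list()
  for (interactor in sort(unique(calls$interactor))) {
    sub <- calls[calls$interactor == interactor, , drop = FALSE]
    kinds <- vapply(sub$variant, function(v) parse_variant(v)$kind, character(1))
    trunc <- sub[kinds %in% c("nonsense", "frameshift"), , drop = FALSE]
    mis <- sub[kinds == "missense", , drop = FALSE]

    required <- NULL
    involved <- character()
    supporting <- character()
    n_pairs <- 0L

    if (nrow(trunc) > 0L) {
      ends <- vapply(trunc$variant, intact_end, numeric(1),
                     variants_df = variants, protein_length = protein_length)
      retaining <- trunc$class %in% c("retained", "reduced")
      losing <- trunc$class == "abolished"
      req_ivs <- list()
      for (i in which(retaining)) {
        for (j in which(losing)) {
          if (ends[j] < ends[i]) {
            req_ivs[[length(req_ivs) + 1L]] <- c(ends[j] + 1, ends[i])
            supporting <- union(supporting, c(trunc$variant[i], trunc$variant[j]))
            n_pairs <- n_pairs + 1L
          }
        }
      }
      if (length(req_ivs) > 0L) required <- intersect_intervals(req_ivs)
      # reduced truncation vs longer fully retained truncation: the
      # differential segment is involved, not strictly required
      for (i in which(trunc$class == "reduced")) {
        for (j in which(trunc$class == "retained")) {
          if (ends[i] < ends[j]) {
            involved <- union(involved,
                              regions_overlapping(c(ends[i] + 1, ends[j]), regions))
            supporting <- union(supporting, c(trunc$variant[i], trunc$variant[j]))
          }
        }
      }
    } else if (nrow(sub) > 0L) {
      warnf("no truncation data for interactor '%s': involvement-only inference",
            interactor)
    }

    missense_losses <- mis$variant[mis$class %in% c("abolished", "reduced")]
    for (v in missense_losses) {
      pos <- parse_variant(v)$position
      involved <- union(involved, regions_overlapping(c(pos, pos), regions))
    }

    required_regions <- regions_overlapping(required, regions)
    dispensable <- character()
    if (nrow(trunc) > 0L) {
      ret_ends <- vapply(trunc$variant[trunc$class == "retained"], intact_end,
                         numeric(1), variants_df = variants,
                         protein_length = protein_length)
      if (length(ret_ends) > 0L) {
        dispensable <- regions$region[regions$start > min(ret_ends)]
      }
    }

    out[[interactor]] <- list(
      required_interval = required,
      required_regions = required_regions,
      involved_regions = sort(union(involved, required_regions)),
      dispensable_regions = dispensable,
      supporting_variants = sort(supporting),
      missense_losses = sort(missense_losses),
      n_truncation_pairs = n_pairs)
  }
  out
}

#' Check a call matrix for truncation-monotonicity violations
#'
#' For a fixed interactor, a strictly shorter intact prefix that retains
#' the interaction while a longer prefix loses it is internally
#' inconsistent (the binding determinant cannot both lie inside and
#' outside the differential segment). "Reduced" counts as retaining.
#' Missense variants are not checked.
#'
#' @inheritParams infer_required_regions
#' @return Data frame of violations: `interactor`, `retained_variant`,
#'   `abolished_variant` (zero rows when consistent).
#' @export
consistency_check <- function(calls, variants, protein_length = 682L) {
  rows <- list()
  if (nrow(calls) > 0L) {
    for (interactor in sort(unique(calls$interactor))) {
      sub <- calls[calls$interactor == interactor, , drop = FALSE]
      kinds <- vapply(sub$variant, function(v) parse_variant(v)$kind, character(1))
      trunc <- sub[kinds %in% c("nonsense", "frameshift"), , drop = FALSE]
      if (nrow(trunc) < 2L) next
      ends <- vapply(trunc$variant, intact_end, numeric(1),
                     variants_df = variants, protein_length = protein_length)
      for (i in which(trunc$class %in% c("retained", "reduced"))) {
        for (j in which(trunc$class == "abolished")) {
          if (ends[i] < ends[j]) {
            rows[[length(rows) + 1L]] <- data.frame(
              interactor = interactor,
              retained_variant = trunc$variant[i],
              abolished_variant = trunc$variant[j],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(interactor = character(), retained_variant = character(),
                      abolished_variant = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Text rendering of the inferred binding-region map
#'
#' @param inference Output of [infer_required_regions()].
#' @return Character vector, one line per interactor.
#' @export
render_region_map <- function(inference) {
  vapply(names(inference), function(nm) {
    inf <- inference[[nm]]
    req <- if (is.null(inf$required_interval)) "none" else
      sprintf("[%d, %d] (%s)", inf$required_interval[1], inf$required_interval[2],
              paste(inf$required_regions, collapse = "+"))
    sprintf("%s: required %s; involved %s; dispensable %s", nm, req,
            if (length(inf$involved_regions)) paste(inf$involved_regions, collapse = ", ") else "none",
            if (length(inf$dispensable_regions)) paste(inf$dispensable_regions, collapse = ", ") else "none")
  }, character(1))
}
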