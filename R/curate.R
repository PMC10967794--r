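#' @title High-confidence curation rules
#' @description Implements the stringent activity-data curation that the
#'   whole analysis rests on: only exact (`"="`) IC50/Ki/Kd measurements in
#'   nM against human single-protein targets are used (for ChEMBL-style
#'   records additionally direct binding assays, relationship `D`, at
#'   confidence score 9); compound-target pairs carrying contradictory
#'   comments lose all their records; replicates of the same endpoint are
#'   pooled on the negative decadic log scale (pPot) and averaged only when
#'   mutually consistent; equilibrium constants (Ki/Kd) take precedence over
#'   IC50; the highest surviving average is the final annotation; and a
#'   minimal potency of 10 uM (pPot 5) is required.
#' @name curate
NULL

#' Convert a potency value in nM to the pPot scale
#'
#' pPot is the negative decadic logarithm of the molar potency, so a value
#' in nM maps to `9 - log10(value)`: 10 uM (10000 nM) gives pPot 5, 1 nM
#' gives pPot 9.
#'
#' @param value numeric vector of potency values in nM, all > 0.
#' @param units character vector of unit labels; must all be `"nM"`.
#' @return numeric vector of pPot values.
#' @export
#' @examples
#' to_ppot(c(10000, 1, 50))
to_ppot <- function(value, units = "nM") {
  units <- rep_len(units, length(value))
  if (any(units != "nM", na.rm = TRUE) || anyNA(units)) {
    pki_abort("unit_mismatch", "pki_unit_mismatch")
  }
  if (anyNA(value) || any(!is.finite(value) | value <= 0)) {
    pki_abort("bad_value", "pki_bad_value")
  }
  9 - log10(value)
}

#' Default high-confidence rule set
#'
#' Per-dialect record-level acceptance rules. ChEMBL-style records must be
#' single-protein, human, direct-binding (`D`) assays at confidence score 9
#' with relation `"="` and unit nM; BindingDB-style records must be human
#' single-protein chains with relation `"="` and a supported endpoint.
#'
#' @return nested list of rule values, editable before passing to
#'   [filter_high_confidence()].
#' @export
default_ruleset <- function() {
  list(
    chembl = list(target_type = "SINGLE PROTEIN", organism = "Homo sapiens",
                  assay_relationship = "D", confidence_score = 9L,
                  relation = "=", units = "nM"),
    bindingdb = list(target_type = "SINGLE PROTEIN",
                     organism = "Homo sapiens", relation = "=", units = "nM")
  )
}

#' Filter activity records to high-confidence measurements
#'
#' Applies the dialect-specific rule chain to every record; a failing record
#' is rejected with the name of the first failed rule (`"target_type"`,
#' `"organism"`, `"assay_relationship"`, `"confidence"`, `"relation"`,
#' `"units"`, `"endpoint"`), never silently dropped.
#'
#' @param records unified activity-record tibble.
#' @param ruleset rule values, see [default_ruleset()].
#' @return list with `accepted` (records tibble) and `rejected` (records
#'   plus a `reason` column).
#' @export
filter_high_confidence <- function(records, ruleset = default_ruleset()) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  fail <- function(cond, why) {
    reason[is.na(reason) & cond] <<- why
  }
  ch <- records$source == "chembl"
  bd <- records$source == "bindingdb"
  rs <- ruleset

  neq <- function(x, v) is.na(x) | x != v
  # ChEMBL chain
  fail(ch & neq(records$target_type, rs$chembl$target_type), "target_type")
  fail(ch & neq(records$organism, rs$chembl$organism), "organism")
  fail(ch & neq(records$assay_relationship, rs$chembl$assay_relationship),
       "assay_relationship")
  fail(ch & neq(records$confidence_score, rs$chembl$confidence_score),
       "confidence")
  fail(ch & neq(records$relation, rs$chembl$relation), "relation")
  fail(ch & neq(records$units, rs$chembl$units), "units")
  # BindingDB chain
  fail(bd & neq(records$organism, rs$bindingdb$organism), "organism")
  fail(bd & neq(records$target_type, rs$bindingdb$target_type), "target_type")
  fail(bd & neq(records$relation, rs$bindingdb$relation), "relation")
  fail(bd & neq(records$units, rs$bindingdb$units), "units")
  # endpoint whitelist (both dialects; normally enforced at parse time)
  fail(!(records$measurement_type %in% c("IC50", "Ki", "Kd")), "endpoint")

  keep <- is.na(reason)
  rejected <- records[!keep, ]
  rejected$reason <- reason[!keep]
  list(accepted = records[keep, ], rejected = rejected)
}

#' Default contradiction vocabulary
#' @return character vector of activity-comment values that mark a
#'   compound-target pair as contradicted.
#' @export
default_contradiction_vocabulary <- function() {
  c("inactive", "inconclusive", "not active")
}

#' Drop compound-target pairs with contradictory annotations
#'
#' If any record of a (compound_key, target_id) pair carries an activity
#' comment in the contradiction vocabulary (case-insensitive), the pair
#' loses all of its records: numbers co-reported with "inactive"-style
#' comments are treated as unreliable rather than averaged away.
#'
#' @param records activity records already carrying `compound_key` and
#'   `target_id` columns.
#' @param vocabulary comment values that mark a contradiction.
#' @return list with `records` (surviving rows) and `dropped_pairs`
#'   (tibble: `compound_key`, `target_id`).
#' @export
drop_contradicted_pairs <- function(records,
                                    vocabulary = default_contradiction_vocabulary()) {
  cmt <- tolower(trimws(ifelse(is.na(records$activity_comment), "",
                               records$activity_comment)))
  flagged <- cmt %in% tolower(vocabulary)
  dropped_pairs <- records[flagged, c("compound_key", "target_id")] |>
    dplyr::distinct() |>
    dplyr::arrange(.data$compound_key, .data$target_id)
  pair_key <- paste(records$compound_key, records$target_id, sep = "\r")
  bad_keys <- unique(pair_key[flagged])
  list(records = records[!(pair_key %in% bad_keys), ],
       dropped_pairs = dropped_pairs)
}

#' Pool replicate pPot values of one measurement group
#'
#' Averages replicates of one endpoint for one compound-target pair iff
#' they are mutually consistent. Under the `span` rule (used for kinase
#' targets) the values must fall in the same order of magnitude:
#' `max - min < cutoff` log units. Under the `sd` rule (used for non-kinase
#' targets) the population standard deviation must not exceed `cutoff`
#' (strictly larger is discarded, the boundary is retained).
#'
#' @param group numeric vector of pPot values (nonempty).
#' @param consistency_rule `"span"` or `"sd"`.
#' @param cutoff consistency cutoff in log units (default 1.0).
#' @return list with `value` (mean, or `NA` when discarded), `discarded`
#'   (logical) and `reason` (`NA`, `"inconsistent_span"` or
#'   `"inconsistent_sd"`).
#' @export
#' @examples
#' pool_and_average(c(6.1, 6.3, 6.2), "span")
#' pool_and_average(c(4.0, 6.5), "sd")
pool_and_average <- function(group, consistency_rule = c("span", "sd"),
                             cutoff = 1.0) {
  consistency_rule <- match.arg(consistency_rule)
  stopifnot(length(group) >= 1L)
  if (consistency_rule == "span") {
    ok <- (max(group) - min(group)) < cutoff
    reason <- if (ok) NA_character_ else "inconsistent_span"
  } else {
    ok <- pop_sd(group) <= cutoff
    reason <- if (ok) NA_character_ else "inconsistent_sd"
  }
  list(value = if (ok) mean(group) else NA_real_,
       discarded = !ok, reason = reason)
}

#' Resolve the final potency annotation of one compound-target pair
#'
#' Equilibrium constants are prioritized: if any consistent Ki or Kd group
#' average survives, the final annotation is the highest of those averages
#' (basis `"equilibrium"`); otherwise a surviving IC50 average is used
#' (basis `"ic50"`); with no surviving group the pair yields nothing.
#'
#' @param groups tibble with columns `measurement_type`, `avg` (group mean
#'   pPot) and `n` (replicate count), one row per surviving group.
#' @return list with `ppot_final`, `basis`, `n_measurements`, or `NULL`.
#' @export
resolve_final_annotation <- function(groups) {
  groups <- groups[!is.na(groups$avg), ]
  if (nrow(groups) == 0L) {
    return(NULL)
  }
  eq <- groups[groups$measurement_type %in% c("Ki", "Kd"), ]
  pick_from <- if (nrow(eq) > 0L) eq else groups[groups$measurement_type == "IC50", ]
  if (nrow(pick_from) == 0L) {
    return(NULL)
  }
  pick_from <- pick_from[order(-pick_from$avg, pick_from$measurement_type,
                               method = "radix"), ]
  list(ppot_final = pick_from$avg[1],
       basis = if (nrow(eq) > 0L) "equilibrium" else "ic50",
       n_measurements = as.integer(pick_from$n[1]))
}

#' Apply the minimal-activity threshold
#'
#' Retains interactions at or above the pPot threshold (default 5,
#' i.e. 10 uM); the boundary is inclusive.
#'
#' @param interactions curated-interaction tibble with `ppot_final`.
#' @param ppot_min minimal pPot (default 5.0).
#' @return filtered tibble.
#' @export
apply_activity_threshold <- function(interactions, ppot_min = 5.0) {
  interactions[interactions$ppot_final >= ppot_min, ]
}

#' Curate activity records into final compound-target interactions
#'
#' Runs the full curation chain: high-confidence record filter, structure
#' standardization and aggregation, target resolution, contradicted-pair
#' removal, per-endpoint replicate pooling (span rule for kinase targets,
#' SD rule for non-kinase targets, cross-source pooling by UniProt-resolved
#' target), equilibrium-over-IC50 prioritization with the highest surviving
#' average as the final annotation, and the minimal-activity threshold.
#'
#' @param records unified activity-record tibble (both dialects may be
#'   mixed).
#' @param targets target-metadata tibble from [read_target_table()].
#' @param ppot_min minimal pPot for retained interactions.
#' @param consistency_cutoff replicate-consistency cutoff in log units.
#' @param consistency_rule `"auto"` (span for kinase, SD for non-kinase
#'   targets), or `"span"`/`"sd"` to force one rule globally.
#' @param vocabulary contradiction vocabulary, see
#'   [default_contradiction_vocabulary()].
#' @param ruleset record-level rules, see [default_ruleset()].
#' @param salt_list canonical salt/solvent forms.
#' @return list with `interactions` (tibble: `compound_key`, `target_id`,
#'   `uniprot`, `is_pk`, `ppot_final`, `basis`, `n_measurements`),
#'   `compounds` (standardized-compound tibble) and `discards` (list of
#'   per-stage discard tibbles: `records`, `structures`, `unknown_targets`,
#'   `contradicted_pairs`, `inconsistent_groups`, `subthreshold_pairs`).
#' @export
curate_interactions <- function(records, targets, ppot_min = 5.0,
                                consistency_cutoff = 1.0,
                                consistency_rule = c("auto", "span", "sd"),
                                vocabulary = default_contradiction_vocabulary(),
                                ruleset = default_ruleset(),
                                salt_list = default_salt_list()) {
  consistency_rule <- match.arg(consistency_rule)

  hc <- filter_high_confidence(records, ruleset)
  agg <- aggregate_compounds(hc$accepted, salt_list = salt_list)
  rec <- agg$records

  # resolve targets: by target_id first, then by UniProt accession
  idx <- match(rec$target_ref, targets$target_id)
  via_up <- is.na(idx) & !is.na(rec$uniprot)
  idx[via_up] <- match(rec$uniprot[via_up], targets$uniprot)
  unknown <- rec[is.na(idx), c("compound_ref", "target_ref", "uniprot")]
  rec <- rec[!is.na(idx), ]
  idx <- idx[!is.na(idx)]
  rec$target_id <- targets$target_id[idx]
  rec$uniprot <- targets$uniprot[idx]
  rec$is_pk <- targets$is_pk[idx]

  ct <- drop_contradicted_pairs(rec, vocabulary = vocabulary)
  rec <- ct$records

  if (nrow(rec) == 0L) {
    empty <- tibble::tibble(compound_key = character(), target_id = character(),
                            uniprot = character(), is_pk = logical(),
                            ppot_final = numeric(), basis = character(),
                            n_measurements = integer())
    return(list(interactions = empty, compounds = agg$compounds,
                discards = list(records = hc$rejected,
                                structures = agg$rejected,
                                unknown_targets = unknown,
                                contradicted_pairs = ct$dropped_pairs,
                                inconsistent_groups = tibble::tibble(),
                                subthreshold_pairs = empty)))
  }

  rec$ppot <- to_ppot(rec$value, rec$units)
  groups <- rec |>
    dplyr::group_by(.data$compound_key, .data$target_id, .data$uniprot,
                    .data$is_pk, .data$measurement_type) |>
    dplyr::summarise(span = max(.data$ppot) - min(.data$ppot),
                     psd = pop_sd(.data$ppot),
                     avg = mean(.data$ppot),
                     n = dplyr::n(), .groups = "drop")
  use_span <- switch(consistency_rule,
                     auto = groups$is_pk,
                     span = rep(TRUE, nrow(groups)),
                     sd = rep(FALSE, nrow(groups)))
  consistent <- ifelse(use_span,
                       groups$span < consistency_cutoff,
                       groups$psd <= consistency_cutoff)
  inconsistent_groups <- groups[!consistent, ] |>
    dplyr::mutate(reason = ifelse(use_span[!consistent],
                                  "inconsistent_span", "inconsistent_sd")) |>
    dplyr::select("compound_key", "target_id", "measurement_type", "n", "reason")
  groups <- groups[consistent, ]

  resolved <- groups |>
    dplyr::group_by(.data$compound_key, .data$target_id, .data$uniprot,
                    .data$is_pk) |>
    dplyr::group_modify(function(g, key) {
      r <- resolve_final_annotation(g[, c("measurement_type", "avg", "n")])
      if (is.null(r)) {
        return(tibble::tibble())
      }
      tibble::tibble(ppot_final = r$ppot_final, basis = r$basis,
                     n_measurements = r$n_measurements)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$compound_key, .data$target_id)

  kept <- apply_activity_threshold(resolved, ppot_min = ppot_min)
  sub <- resolved[resolved$ppot_final < ppot_min, ]

  list(interactions = kept, compounds = agg$compounds,
       discards = list(records = hc$rejected,
                       structures = agg$rejected,
                       unknown_targets = unknown,
                       contradicted_pairs = ct$dropped_pairs,
                       inconsistent_groups = inconsistent_groups,
                       subthreshold_pairs = sub))
}
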