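#' @title Promiscuity degrees and ranking reports
#' @description A compound's kinase promiscuity degree (PK_PD) is the
#'   number of distinct protein kinases it is active against at the curation
#'   threshold; the non-kinase promiscuity degree (Non-PK_PD) counts its
#'   non-kinase targets. The analysis set comprises exactly the compounds
#'   with at least one kinase and at least one non-kinase target. This
#'   module builds those profiles, bins their distributions, ranks targets
#'   by shared inhibitors, ranks compounds by non-kinase target counts, and
#'   scans interaction counts over increasing potency thresholds.
#' @name promiscuity
NULL

#' Build promiscuity profiles (the analysis set)
#'
#' One profile per compound with `pk_pd >= 1` and `nonpk_pd >= 1`;
#' compounds active only against kinases (or only against non-kinases) are
#' excluded by construction.
#'
#' @param interactions curated-interaction tibble (already thresholded).
#' @param targets target-metadata tibble; every interaction target must be
#'   present (a missing target is a fatal error naming the ID).
#' @return tibble with `compound_key`, `pk_targets` and `nonpk_targets`
#'   (list-columns of sorted target IDs), `pk_pd`, `nonpk_pd`.
#' @export
build_profiles <- function(interactions, targets) {
  missing <- setdiff(unique(interactions$target_id), targets$target_id)
  if (length(missing) > 0L) {
    pki_abort(paste0("targets absent from metadata: ",
                     paste(missing, collapse = ", ")), "pki_unknown_target")
  }
  is_pk <- targets$is_pk[match(interactions$target_id, targets$target_id)]
  interactions$is_pk <- is_pk
  prof <- interactions |>
    dplyr::group_by(.data$compound_key) |>
    dplyr::summarise(
      pk_targets = list(sort(unique(.data$target_id[.data$is_pk]))),
      nonpk_targets = list(sort(unique(.data$target_id[!.data$is_pk]))),
      .groups = "drop"
    ) |>
    dplyr::mutate(pk_pd = lengths(.data$pk_targets),
                  nonpk_pd = lengths(.data$nonpk_targets)) |>
    dplyr::filter(.data$pk_pd >= 1L, .data$nonpk_pd >= 1L) |>
    dplyr::arrange(.data$compound_key)
  prof
}

#' Default promiscuity-degree bins
#'
#' Single target, two to four, five to nine, ten or more.
#'
#' @return named list of `c(lo, hi)` integer ranges (`Inf` = open-ended).
#' @export
default_pd_bins <- function() {
  list("1" = c(1, 1), "2-4" = c(2, 4), "5-9" = c(5, 9), "10+" = c(10, Inf))
}

#' Bin a promiscuity-degree distribution
#'
#' Counts profiles per degree bin and reports percentages of the analysis
#' set, rounded half up to one decimal (printed-report style). The bins
#' must partition the positive integers: overlaps or gaps are fatal.
#'
#' @param profiles profile tibble from [build_profiles()].
#' @param which `"pk"` or `"nonpk"`: which degree to bin.
#' @param bins ordered list of `c(lo, hi)` ranges, see [default_pd_bins()].
#' @return tibble with `bin`, `lo`, `hi`, `count`, `percentage`.
#' @export
bin_distribution <- function(profiles, which = c("pk", "nonpk"),
                             bins = default_pd_bins()) {
  which <- match.arg(which)
  lo <- vapply(bins, `[`, 0, 1L)
  hi <- vapply(bins, `[`, 0, 2L)
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  if (lo[1] != 1 || any(hi < lo) ||
      (length(lo) > 1L && any(lo[-1] != hi[-length(hi)] + 1)) ||
      is.finite(hi[length(hi)])) {
    pki_abort("bins must partition the positive integers", "pki_bad_bins")
  }
  deg <- if (which == "pk") profiles$pk_pd else profiles$nonpk_pd
  count <- vapply(seq_along(lo), function(i) {
    sum(deg >= lo[i] & deg <= hi[i])
  }, 0L)
  total <- nrow(profiles)
  tibble::tibble(
    bin = names(bins)[ord],
    lo = lo, hi = hi, count = count,
    percentage = if (total > 0L) round_half_up(100 * count / total, 1) else rep(0, length(count))
  )
}

#' Rank targets by numbers of shared inhibitors
#'
#' For the kinase domain: per kinase, the number of analysis-set compounds
#' active against it and the number of distinct non-kinase targets those
#' compounds engage (the counterpart count). The non-kinase domain is
#' symmetric. Sorted by shared-inhibitor count (descending), ties broken by
#' target ID.
#'
#' @param profiles profile tibble from [build_profiles()].
#' @param domain `"pk"` or `"nonpk"`.
#' @param k number of rows to return (`Inf` = all).
#' @param targets optional target-metadata tibble; when given, `name` and
#'   group/class columns are joined on.
#' @return tibble with `target_id`, `n_shared_pkis`,
#'   `n_counterpart_targets` (+ metadata columns when `targets` is given).
#' @export
rank_targets_by_shared_inhibitors <- function(profiles,
                                              domain = c("pk", "nonpk"),
                                              k = 10, targets = NULL) {
  domain <- match.arg(domain)
  own <- if (domain == "pk") profiles$pk_targets else profiles$nonpk_targets
  other <- if (domain == "pk") profiles$nonpk_targets else profiles$pk_targets
  long <- tibble::tibble(
    target_id = unlist(own),
    compound = rep(seq_len(nrow(profiles)), lengths(own))
  )
  ranked <- long |>
    dplyr::group_by(.data$target_id) |>
    dplyr::summarise(
      n_shared_pkis = dplyr::n_distinct(.data$compound),
      n_counterpart_targets = length(unique(unlist(other[.data$compound]))),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_shared_pkis), .data$target_id)
  if (!is.null(targets)) {
    meta_cols <- intersect(c("target_id", "name", "kinase_group", "class_l1"),
                           names(targets))
    ranked <- dplyr::left_join(ranked, targets[, meta_cols], by = "target_id")
  }
  utils::head(ranked, k)
}

#' Rank compounds by numbers of non-kinase targets
#'
#' Sorted by `nonpk_pd` (descending), ties by `pk_pd` (descending) then
#' compound key.
#'
#' @param profiles profile tibble.
#' @param k number of rows (`Inf` = all).
#' @return tibble with `compound_key`, `nonpk_pd`, `pk_pd`.
#' @export
rank_compounds_by_nonpk_targets <- function(profiles, k = 10) {
  out <- profiles[order(-profiles$nonpk_pd, -profiles$pk_pd,
                        profiles$compound_key, method = "radix"),
                  c("compound_key", "nonpk_pd", "pk_pd")]
  utils::head(out, k)
}

#' Scan unique target counts over potency thresholds
#'
#' For each threshold, counts the unique kinase and non-kinase targets of
#' the analysis-set compounds (defined at the base threshold, the smallest
#' one) among interactions at or above the threshold. Both columns are
#' non-increasing in the threshold.
#'
#' @param interactions curated-interaction tibble with `ppot_final`.
#' @param targets target-metadata tibble.
#' @param thresholds increasing pPot thresholds (default `c(5, 6, 7, 8)`).
#' @return tibble with `ppot_threshold`, `unique_pk_targets`,
#'   `unique_nonpk_targets`.
#' @export
potency_scan <- function(interactions, targets, thresholds = c(5, 6, 7, 8)) {
  thresholds <- sort(thresholds)
  base <- apply_activity_threshold(interactions, ppot_min = thresholds[1])
  prof <- build_profiles(base, targets)
  pool <- base[base$compound_key %in% prof$compound_key, ]
  is_pk <- targets$is_pk[match(pool$target_id, targets$target_id)]
  rows <- lapply(thresholds, function(t) {
    at <- pool$ppot_final >= t
    tibble::tibble(
      ppot_threshold = t,
      unique_pk_targets = length(unique(pool$target_id[at & is_pk])),
      unique_nonpk_targets = length(unique(pool$target_id[at & !is_pk]))
    )
  })
  dplyr::bind_rows(rows)
}

#' Count compounds with a nanomolar non-kinase primary target and only
#' micromolar kinase activity
#'
#' Identifies analysis-set compounds whose strongest non-kinase activity is
#' at least `nonpk_min` (nanomolar by default, pPot >= 7) while their
#' strongest kinase activity sits in the micromolar band
#' `[pk_band[1], pk_band[2])` — compounds that formally qualify as kinase
#' inhibitors but are primarily active against other targets.
#'
#' @param interactions curated-interaction tibble.
#' @param targets target-metadata tibble.
#' @param nonpk_min minimal max non-kinase pPot (default 7.0).
#' @param pk_band half-open micromolar band for the max kinase pPot
#'   (default `c(5, 6)`).
#' @return list with `count` and `compounds` (character vector of keys).
#' @export
count_inverted_primary <- function(interactions, targets, nonpk_min = 7.0,
                                   pk_band = c(5.0, 6.0)) {
  prof <- build_profiles(interactions, targets)
  pool <- interactions[interactions$compound_key %in% prof$compound_key, ]
  is_pk <- targets$is_pk[match(pool$target_id, targets$target_id)]
  mx <- tibble::tibble(compound_key = pool$compound_key,
                       is_pk = is_pk, ppot = pool$ppot_final) |>
    dplyr::group_by(.data$compound_key) |>
    dplyr::summarise(
      pk_max = max(.data$ppot[.data$is_pk]),
      nonpk_max = max(.data$ppot[!.data$is_pk]),
      .groups = "drop"
    )
  hit <- mx$nonpk_max >= nonpk_min & mx$pk_max >= pk_band[1] & mx$pk_max < pk_band[2]
  list(count = sum(hit), compounds = sort(mx$compound_key[hit]))
}

#' Write promiscuity profiles in the deposited-annotation schema
#'
#' Columns: `smiles` (compound key), `pk_pd`, `nonpk_pd`,
#' `pk_target_ids`, `nonpk_target_ids` (semicolon-separated).
#'
#' @param profiles profile tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_file <- function(profiles, path) {
  out <- tibble::tibble(
    smiles = profiles$compound_key,
    pk_pd = profiles$pk_pd,
    nonpk_pd = profiles$nonpk_pd,
    pk_target_ids = vapply(profiles$pk_targets, paste, "", collapse = ";"),
    nonpk_target_ids = vapply(profiles$nonpk_targets, paste, "", collapse = ";")
  )
  write_table(out, path)
}

#' Read promiscuity profiles from a deposited-annotation file
#'
#' Reads the compound annotation schema written by
#' [write_annotation_file()] (compound SMILES, PK_PD, Non-PK_PD and
#' semicolon-separated target ID lists) back into a profile tibble, so that
#' network construction and summaries can be recomputed from a published
#' annotation file alone.
#'
#' @param path TSV/CSV path.
#' @param column_map optional named character vector mapping the canonical
#'   names (`smiles`, `pk_pd`, `nonpk_pd`, `pk_target_ids`,
#'   `nonpk_target_ids`) to the file's column names.
#' @return profile tibble as from [build_profiles()].
#' @export
read_annotation_file <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    pki_abort(paste0("annotation file not found: ", path), "pki_io_error")
  }
  cols <- c(smiles = "smiles", pk_pd = "pk_pd", nonpk_pd = "nonpk_pd",
            pk_target_ids = "pk_target_ids",
            nonpk_target_ids = "nonpk_target_ids")
  if (!is.null(column_map)) {
    cols[names(column_map)] <- unname(column_map)
  }
  raw <- readr::read_delim(path, delim = detect_delim(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0L) {
    pki_abort(paste0("annotation file lacks columns: ",
                     paste(missing_cols, collapse = ", ")), "pki_io_error")
  }
  split_ids <- function(x) {
    lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
           function(v) sort(v[nzchar(v)]))
  }
  tibble::tibble(
    compound_key = raw[[cols["smiles"]]],
    pk_targets = split_ids(raw[[cols["pk_target_ids"]]]),
    nonpk_targets = split_ids(raw[[cols["nonpk_target_ids"]]]),
    pk_pd = as.integer(raw[[cols["pk_pd"]]]),
    nonpk_pd = as.integer(raw[[cols["nonpk_pd"]]])
  )
}
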