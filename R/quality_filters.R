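#' @title Assay-interference and anti-target screening
#' @description False-positive activity annotations are the main error
#'   source in promiscuity assessment, so compounds matching pan-assay
#'   interference (PAINS-style) substructures or reactive-chemistry alerts
#'   are removed, as are compounds with reported activity against
#'   anti-targets (hERG-like liabilities). All three filters are
#'   compound-level predicates, so their application order does not affect
#'   the final compound set.
#' @name quality_filters
NULL

#' Load a named substructure-pattern catalog
#'
#' Pattern files are TSV with columns `name` and `smarts`, `#` comments
#' allowed. Every pattern is compiled against a probe molecule at load
#' time; a malformed pattern is a fatal error naming the pattern.
#'
#' @param path pattern file; the package ships `interference_patterns.tsv`
#'   (a PAINS-style subset) and `chemistry_rules.tsv` (reactive /
#'   assay-hostile motifs) under `extdata`.
#' @return tibble with `name`, `smarts`.
#' @export
load_pattern_catalog <- function(path) {
  if (!file.exists(path)) {
    pki_abort(paste0("pattern catalog not found: ", path), "pki_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) > 0L && identical(tolower(parts[[1]][1]), "name")) {
    parts <- parts[-1]
  }
  cat <- tibble::tibble(
    name = vapply(parts, `[`, "", 1L),
    smarts = vapply(parts, `[`, "", 2L)
  )
  if (anyNA(cat$smarts) || any(!nzchar(cat$smarts))) {
    pki_abort("pattern catalog rows need <name>\t<smarts>", "pki_io_error")
  }
  for (i in seq_len(nrow(cat))) {
    ok <- tryCatch({
      ChemmineOB::forEachMol("SMILES", "C", function(mol) {
        ChemmineOB::smartsSearch_OB(list(mol), cat$smarts[i])
      })
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      pki_abort(paste0("malformed substructure pattern: ", cat$name[i]),
                "pki_bad_pattern")
    }
  }
  cat
}

#' Screen compounds against a substructure catalog
#'
#' Returns one verdict per compound key: `passed` is `TRUE` iff no pattern
#' in the catalog matches. Deterministic for a fixed catalog and idempotent.
#'
#' @param compound_keys character vector of standardized structure keys.
#' @param catalog pattern tibble from [load_pattern_catalog()].
#' @param stage label recorded on the verdicts (`"interference"` or
#'   `"chemistry_rules"`).
#' @return tibble with `compound_key`, `passed`, `matched_rules`
#'   (list-column of matched pattern names) and `stage`.
#' @export
screen_substructures <- function(compound_keys, catalog,
                                 stage = "interference") {
  keys <- unique(compound_keys)
  matched <- vector("list", length(keys))
  if (length(keys) > 0L) {
    hits <- ChemmineOB::forEachMol(
      "SMILES", paste(keys, collapse = "\n"),
      function(mol) {
        vapply(catalog$smarts, function(p) {
          as.numeric(ChemmineOB::smartsSearch_OB(list(mol), p)[[1]]) > 0
        }, TRUE, USE.NAMES = FALSE)
      }
    )
    matched <- lapply(hits, function(h) catalog$name[h])
  }
  tibble::tibble(
    compound_key = keys,
    passed = lengths(matched) == 0L,
    matched_rules = matched,
    stage = stage
  )[order(keys, method = "radix"), ]
}

#' Remove compounds active against anti-targets
#'
#' Any compound with at least one retained interaction against a target
#' flagged `is_antitarget` loses all of its interactions. By default any
#' reported activity triggers removal; set `min_ppot` to require a potency
#' level.
#'
#' @param interactions curated-interaction tibble.
#' @param targets target-metadata tibble.
#' @param min_ppot optional pPot an anti-target interaction must reach to
#'   trigger removal (`NULL` = any reported activity).
#' @return list with `clean` (interaction tibble without the removed
#'   compounds and without anti-target rows) and `removed` (tibble:
#'   `compound_key`, `trigger_targets`).
#' @export
screen_antitargets <- function(interactions, targets, min_ppot = NULL) {
  at_ids <- targets$target_id[targets$is_antitarget]
  is_at <- interactions$target_id %in% at_ids
  trig <- is_at
  if (!is.null(min_ppot)) {
    trig <- trig & interactions$ppot_final >= min_ppot
  }
  removed <- interactions[trig, ] |>
    dplyr::group_by(.data$compound_key) |>
    dplyr::summarise(trigger_targets = list(sort(unique(.data$target_id))),
                     .groups = "drop") |>
    dplyr::arrange(.data$compound_key)
  clean <- interactions[!(interactions$compound_key %in% removed$compound_key) &
                          !is_at, ]
  list(clean = clean, removed = removed)
}

#' Apply all compound-level quality filters
#'
#' Interference screening, chemistry-rule screening and anti-target removal
#' combined; the surviving interaction set is independent of filter order.
#'
#' @param interactions curated-interaction tibble.
#' @param targets target-metadata tibble.
#' @param interference_catalog,chemistry_catalog pattern tibbles; `NULL`
#'   loads the shipped defaults.
#' @param antitarget_min_ppot see [screen_antitargets()].
#' @return list with `interactions` (surviving), `verdicts` (all
#'   substructure verdicts), `removed_interference`, `removed_chemistry`
#'   (character vectors of compound keys) and `removed_antitarget` (tibble).
#' @export
apply_quality_filters <- function(interactions, targets,
                                  interference_catalog = NULL,
                                  chemistry_catalog = NULL,
                                  antitarget_min_ppot = NULL) {
  if (is.null(interference_catalog)) {
    interference_catalog <- load_pattern_catalog(
      system.file("extdata", "interference_patterns.tsv", package = "pkitargets"))
  }
  if (is.null(chemistry_catalog)) {
    chemistry_catalog <- load_pattern_catalog(
      system.file("extdata", "chemistry_rules.tsv", package = "pkitargets"))
  }
  keys <- unique(interactions$compound_key)
  v1 <- screen_substructures(keys, interference_catalog, stage = "interference")
  v2 <- screen_substructures(keys, chemistry_catalog, stage = "chemistry_rules")
  bad1 <- v1$compound_key[!v1$passed]
  bad2 <- v2$compound_key[!v2$passed]
  kept <- interactions[!(interactions$compound_key %in% c(bad1, bad2)), ]
  at <- screen_antitargets(kept, targets, min_ppot = antitarget_min_ppot)
  list(interactions = at$clean,
       verdicts = dplyr::bind_rows(v1, v2),
       removed_interference = bad1,
       removed_chemistry = bad2,
       removed_antitarget = at$removed)
}
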