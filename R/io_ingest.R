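#' @title Activity-table ingestion
#' @description Readers for ChEMBL-style and BindingDB-style flat activity
#'   exports and the target-metadata table, plus a deterministic TSV writer.
#'   Both dialects are parsed into one unified activity-record model so that
#'   downstream curation rules can treat them uniformly while still applying
#'   dialect-specific confidence criteria (ChEMBL exports carry assay
#'   relationship and confidence-score columns that BindingDB exports lack;
#'   absent fields stay `NA`, they are never defaulted).
#' @name io_ingest
NULL

# Canonical (pipeline-internal) column names per dialect. A column_map given
# to read_activity_table() maps canonical name -> column name in the file.
.chembl_cols <- c(
  compound_id = "compound_id", smiles = "smiles", target_id = "target_id",
  uniprot = "uniprot", organism = "organism", target_type = "target_type",
  assay_relationship = "assay_relationship",
  confidence_score = "confidence_score", standard_type = "standard_type",
  standard_relation = "standard_relation", standard_value = "standard_value",
  standard_units = "standard_units", activity_comment = "activity_comment"
)
.chembl_mandatory <- c(
  "compound_id", "smiles", "target_id", "organism", "target_type",
  "standard_type", "standard_relation", "standard_value", "standard_units"
)

.bindingdb_cols <- c(
  compound_id = "compound_id", smiles = "smiles", target_id = "target_id",
  uniprot = "uniprot", organism = "organism", n_chains = "n_chains",
  measurement_type = "measurement_type", relation = "relation",
  value = "value", units = "units", activity_comment = "activity_comment"
)
.bindingdb_mandatory <- c(
  "compound_id", "smiles", "target_id", "organism", "measurement_type",
  "value"
)

.endpoints <- c("IC50", "Ki", "Kd")

# Normalize an endpoint label; NA if it is not one of the three supported
# potency endpoints (single-point readouts such as "% inhibition" are out).
normalize_endpoint <- function(x) {
  key <- toupper(trimws(x))
  out <- .endpoints[match(key, toupper(.endpoints))]
  out
}

#' Read an activity table into unified activity records
#'
#' Parses one flat activity export into the unified record model. The
#' delimiter (tab or comma) is auto-detected from the header line. Rows that
#' cannot be represented are not dropped silently: they are returned in a
#' `rejected` tibble with a machine-readable reason (`"unsupported_endpoint"`,
#' `"bad_value"`, `"missing_field"`).
#'
#' @param path path to a TSV/CSV activity export.
#' @param dialect `"chembl"` or `"bindingdb"`.
#' @param column_map optional named character vector mapping canonical column
#'   names (see details) to the column names actually present in the file.
#' @return a list of class `pki_ingest` with elements `records` (tibble, one
#'   row per accepted measurement) and `rejected` (tibble with `row`,
#'   `compound_ref`, `reason`).
#' @details Unified record fields: `source`, `compound_ref`, `smiles_raw`,
#'   `target_ref`, `uniprot`, `organism`, `target_type`,
#'   `assay_relationship`, `confidence_score`, `measurement_type`,
#'   `relation`, `value`, `units`, `activity_comment`. BindingDB rows derive
#'   `target_type` from the chain count (`1` chain = `"SINGLE PROTEIN"`);
#'   assay relationship and confidence score stay absent for that dialect.
#' @export
read_activity_table <- function(path, dialect = c("chembl", "bindingdb"),
                                column_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    pki_abort(paste0("activity table not found: ", path), "pki_io_error")
  }
  spec_cols <- if (dialect == "chembl") .chembl_cols else .bindingdb_cols
  mandatory <- if (dialect == "chembl") .chembl_mandatory else .bindingdb_mandatory
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(spec_cols))
    if (length(bad) > 0L) {
      pki_abort(paste0("unknown canonical columns in column_map: ",
                       paste(bad, collapse = ", ")), "pki_io_error")
    }
    spec_cols[names(column_map)] <- unname(column_map)
  }

  raw <- readr::read_delim(path, delim = detect_delim(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(unname(spec_cols[mandatory]), names(raw))
  if (length(missing_cols) > 0L) {
    pki_abort(paste0("mandatory columns absent from ", path, ": ",
                     paste(missing_cols, collapse = ", ")), "pki_io_error")
  }

  get_col <- function(canon) {
    col <- spec_cols[[canon]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }

  n <- nrow(raw)
  if (dialect == "chembl") {
    rec <- tibble::tibble(
      source = rep("chembl", n),
      compound_ref = get_col("compound_id"),
      smiles_raw = get_col("smiles"),
      target_ref = get_col("target_id"),
      uniprot = get_col("uniprot"),
      organism = get_col("organism"),
      target_type = get_col("target_type"),
      assay_relationship = get_col("assay_relationship"),
      confidence_score = suppressWarnings(as.integer(get_col("confidence_score"))),
      measurement_type_raw = get_col("standard_type"),
      relation = get_col("standard_relation"),
      value_raw = get_col("standard_value"),
      units = get_col("standard_units"),
      activity_comment = get_col("activity_comment")
    )
  } else {
    n_chains <- suppressWarnings(as.integer(get_col("n_chains")))
    target_type <- ifelse(is.na(n_chains) | n_chains == 1L,
                          "SINGLE PROTEIN", "PROTEIN COMPLEX")
    relation <- get_col("relation")
    relation[is.na(relation)] <- "="
    units <- get_col("units")
    units[is.na(units)] <- "nM"
    rec <- tibble::tibble(
      source = rep("bindingdb", n),
      compound_ref = get_col("compound_id"),
      smiles_raw = get_col("smiles"),
      target_ref = get_col("target_id"),
      uniprot = get_col("uniprot"),
      organism = get_col("organism"),
      target_type = target_type,
      assay_relationship = rep(NA_character_, n),
      confidence_score = rep(NA_integer_, n),
      measurement_type_raw = get_col("measurement_type"),
      relation = relation,
      value_raw = get_col("value"),
      units = units,
      activity_comment = get_col("activity_comment")
    )
  }

  rec$measurement_type <- normalize_endpoint(rec$measurement_type_raw)
  rec$value <- suppressWarnings(as.numeric(rec$value_raw))
  rec$row <- seq_len(max(n, 0L))

  # first failed check names the rejection reason
  miss <- Reduce(`|`, lapply(mandatory, function(canon) {
    v <- rec[[switch(canon,
                     compound_id = "compound_ref", smiles = "smiles_raw",
                     target_id = "target_ref",
                     standard_type = "measurement_type_raw",
                     measurement_type = "measurement_type_raw",
                     standard_relation = "relation",
                     standard_value = "value_raw", value = "value_raw",
                     standard_units = "units", canon)]]
    is.na(v) | (is.character(v) & !nzchar(v))
  }), rep(FALSE, n))
  reason <- rep(NA_character_, n)
  reason[miss] <- "missing_field"
  bad_ep <- !miss & is.na(rec$measurement_type)
  reason[bad_ep] <- "unsupported_endpoint"
  bad_val <- is.na(reason) & (is.na(rec$value) | !is.finite(rec$value) | rec$value <= 0)
  reason[bad_val] <- "bad_value"

  keep <- is.na(reason)
  records <- rec[keep, c("source", "compound_ref", "smiles_raw", "target_ref",
                         "uniprot", "organism", "target_type",
                         "assay_relationship", "confidence_score",
                         "measurement_type", "relation", "value", "units",
                         "activity_comment")]
  rejected <- tibble::tibble(
    row = rec$row[!keep],
    compound_ref = rec$compound_ref[!keep],
    reason = reason[!keep]
  )
  structure(list(records = records, rejected = rejected),
            class = "pki_ingest")
}

#' The ten level-1 target classes
#'
#' Level-1 protein classes of the ChEMBL-style classification used to bin
#' non-kinase targets.
#'
#' @return character vector of the ten class names.
#' @export
chembl_class_levels <- function() {
  c("Enzyme", "Membrane receptor", "Epigenetic regulator", "Ion channel",
    "Transcription factor", "Transporter", "Secreted protein",
    "Cytosolic other protein", "Other", "Unclassified")
}

#' Kinase group names of the human kinome tree
#'
#' @return character vector of accepted kinase phylogenetic group labels.
#' @export
kinase_groups <- function() {
  c("TK", "TKL", "AGC", "CAMK", "CMGC", "CK1", "STE", "Other/Atypical")
}

#' Read the target-metadata table
#'
#' Columns: `target_id`, `uniprot`, `name`, `is_pk`, `kinase_group`,
#' `class_l1`, `class_l2`, `is_antitarget`. A duplicated `target_id` is a
#' fatal error naming the ID; a kinase row without a kinase group, a row
#' flagged both kinase and anti-target, or an unknown level-1 class is
#' rejected with a reason.
#'
#' @param path path to a TSV/CSV target table.
#' @param class_levels allowed level-1 class names.
#' @return tibble of target entries keyed by `target_id`, with a `rejected`
#'   attribute holding the per-row rejection tibble.
#' @export
read_target_table <- function(path, class_levels = chembl_class_levels()) {
  if (!file.exists(path)) {
    pki_abort(paste0("target table not found: ", path), "pki_io_error")
  }
  raw <- readr::read_delim(path, delim = detect_delim(path),
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  needed <- c("target_id", "uniprot", "name", "is_pk", "class_l1")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    pki_abort(paste0("target table lacks columns: ",
                     paste(missing_cols, collapse = ", ")), "pki_io_error")
  }
  dup <- raw$target_id[duplicated(raw$target_id)]
  if (length(dup) > 0L) {
    pki_abort(paste0("duplicated target_id in ", path, ": ",
                     paste(unique(dup), collapse = ", ")),
              "pki_duplicate_target")
  }
  as_flag <- function(x) toupper(trimws(x)) %in% c("TRUE", "T", "1", "YES")
  tab <- tibble::tibble(
    target_id = raw$target_id,
    uniprot = raw$uniprot,
    name = raw$name,
    is_pk = as_flag(raw$is_pk),
    kinase_group = if ("kinase_group" %in% names(raw)) raw$kinase_group else NA_character_,
    class_l1 = raw$class_l1,
    class_l2 = if ("class_l2" %in% names(raw)) raw$class_l2 else NA_character_,
    is_antitarget = if ("is_antitarget" %in% names(raw)) as_flag(raw$is_antitarget) else FALSE
  )
  tab$kinase_group[!is.na(tab$kinase_group) & !nzchar(trimws(tab$kinase_group))] <- NA_character_

  reason <- rep(NA_character_, nrow(tab))
  reason[tab$is_pk & (is.na(tab$kinase_group) |
                        !(tab$kinase_group %in% kinase_groups()))] <- "missing_kinase_group"
  reason[is.na(reason) & tab$is_pk & tab$is_antitarget] <- "antitarget_pk_conflict"
  reason[is.na(reason) & !(tab$class_l1 %in% class_levels)] <- "unknown_class"

  rejected <- tibble::tibble(target_id = tab$target_id[!is.na(reason)],
                             reason = reason[!is.na(reason)])
  out <- tab[is.na(reason), ]
  attr(out, "rejected") <- rejected
  out
}

#' Write a pipeline artifact as a deterministic TSV
#'
#' UTF-8, tab-separated, header included. Rows are sorted by the first
#' column, with remaining columns as tie-breaks, so identical inputs always
#' produce byte-identical files. List columns are collapsed with `";"`.
#'
#' @param records data frame / tibble to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (is.null(records) || !is.data.frame(records)) {
    pki_abort("write_table() needs a data frame", "pki_io_error")
  }
  out <- tibble::as_tibble(records)
  for (col in names(out)) {
    if (is.list(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(v) paste(v, collapse = ";"), "")
    }
  }
  if (nrow(out) > 0L) {
    out <- out[do.call(order, c(unname(as.list(out)), list(method = "radix"))), ]
  }
  ok <- tryCatch({
    readr::write_tsv(out, path, progress = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    pki_abort(paste0("cannot write table to ", path), "pki_io_error")
  }
  invisible(path)
}
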