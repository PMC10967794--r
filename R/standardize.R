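#' @title Compound structure standardization
#' @description Measurements are pooled per compound under a structure key
#'   that is invariant to salt form, protonation state, stereochemistry and
#'   isotope labelling: the non-stereo canonical SMILES of the neutralized
#'   parent component. Canonicalization is delegated to OpenBabel (via
#'   ChemmineOB); the salt-stripping rule is: split into covalently
#'   connected components, drop components without carbon, drop components
#'   on the salt/solvent list unless that would drop the last fragment
#'   standing (so a lone small acid, or an ethanol-HCl pair, still yields a
#'   parent), keep the largest remaining component by heavy atom count
#'   (tie: lexicographically smallest canonical form). Neutralization uses OpenBabel's
#'   `neutralize` operation, which adjusts +1/-1 protonation states and
#'   leaves permanently charged centers (e.g. quaternary N) untouched.
#' @name standardize
NULL

.pki_env <- new.env(parent = emptyenv())

# Batch SMILES -> canonical SMILES via OpenBabel, robust to unparseable
# rows. OpenBabel stops a batch at the first bad molecule, so inputs are
# tagged with index titles and re-submitted until every row is classified;
# bad rows come back as NA.
ob_canonicalize <- function(smiles, neutralize = TRUE) {
  out <- rep(NA_character_, length(smiles))
  todo <- which(!is.na(smiles) & nzchar(trimws(smiles)))
  opts <- if (neutralize) data.frame(names = "neutralize", args = "") else NULL
  while (length(todo) > 0L) {
    input <- paste0(smiles[todo], " m", todo, collapse = "\n")
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", input, options = opts),
      error = function(e) ""
    )
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    got <- integer(0)
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) >= 2L && grepl("^m[0-9]+$", parts[2])) {
        idx <- as.integer(sub("^m", "", parts[2]))
        out[idx] <- parts[1]
        got <- c(got, idx)
      }
    }
    remaining <- setdiff(todo, got)
    if (length(remaining) == length(todo)) {
      # nothing converted: first remaining row is bad, drop it and retry
      remaining <- remaining[-1]
    } else if (length(remaining) > 0L) {
      # OpenBabel halted: the first unconverted row is the bad one
      remaining <- remaining[-1]
    }
    todo <- remaining
  }
  out
}

# Per-component properties: non-stereo canonical SMILES, carbon presence,
# heavy atom count. Components must already be OpenBabel-parseable.
ob_component_info <- function(components) {
  if (length(components) == 0L) {
    return(tibble::tibble(component = character(), cansmi_ns = character(),
                          has_carbon = logical(), heavy_atoms = integer()))
  }
  props <- ChemmineOB::forEachMol(
    "SMILES", paste(components, collapse = "\n"),
    function(mol) ChemmineOB::prop_OB(mol)
  )
  parse_formula <- function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    el <- sub("[0-9]*$", "", toks)
    cnt <- as.integer(sub("^[A-Z][a-z]?", "", toks))
    cnt[is.na(cnt)] <- 1L
    list(carbon = sum(cnt[el == "C"]), heavy = sum(cnt[el != "H"]))
  }
  info <- lapply(props, function(p) {
    f <- parse_formula(p$formula[1])
    list(ns = p$cansmiNS[1], c = f$carbon, h = f$heavy)
  })
  tibble::tibble(
    component = components,
    cansmi_ns = vapply(info, function(x) x$ns, ""),
    has_carbon = vapply(info, function(x) x$c > 0L, TRUE),
    heavy_atoms = vapply(info, function(x) as.integer(x$h), 1L)
  )
}

#' Default salt/solvent list
#'
#' Reads the shipped salt/solvent SMILES list (one pattern per line, `#`
#' comments allowed) and returns the standardized (neutralized, non-stereo
#' canonical) forms used for component matching. Cached per session.
#'
#' @param path path to a salt list file; defaults to the shipped list.
#' @return character vector of canonical salt/solvent component forms.
#' @export
default_salt_list <- function(path = system.file("extdata", "salt_solvent_list.txt",
                                                 package = "pkitargets")) {
  key <- paste0("salts::", path)
  if (!is.null(.pki_env[[key]])) {
    return(.pki_env[[key]])
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  can <- ob_canonicalize(lines, neutralize = TRUE)
  info <- ob_component_info(unique(can[!is.na(can)]))
  salts <- sort(unique(info$cansmi_ns))
  .pki_env[[key]] <- salts
  salts
}

#' Standardize structures to aggregation keys
#'
#' Maps raw SMILES to the compound aggregation key: neutralized, salt- and
#' stereo-free canonical SMILES of the parent component. Vectorized;
#' unparseable structures yield `NA` with reason `"bad_structure"`, inputs
#' whose components are all salt-list/carbon-free yield `NA` with reason
#' `"no_organic_component"`. Standardization is idempotent: applying it to a
#' returned key returns the same key.
#'
#' @param smiles character vector of raw SMILES.
#' @param salt_list canonical salt/solvent forms (see [default_salt_list()]).
#' @return character vector of compound keys (`NA` where rejected) with a
#'   `rejected` attribute: tibble of `smiles_raw`, `reason`.
#' @export
#' @examples
#' \donttest{
#' standardize_structure(c("CCO.Cl", "C[C@@H](N)C(=O)O", "CC(=O)[O-].[Na+]"))
#' }
standardize_structure <- function(smiles, salt_list = default_salt_list()) {
  keys <- rep(NA_character_, length(smiles))
  reasons <- rep(NA_character_, length(smiles))
  uniq <- unique(smiles[!is.na(smiles) & nzchar(trimws(smiles))])
  if (length(uniq) > 0L) {
    can <- ob_canonicalize(uniq, neutralize = TRUE)
    comp_lists <- strsplit(ifelse(is.na(can), "", can), ".", fixed = TRUE)
    all_comps <- unique(unlist(comp_lists))
    all_comps <- all_comps[nzchar(all_comps)]
    info <- ob_component_info(all_comps)
    ukeys <- rep(NA_character_, length(uniq))
    ureasons <- rep(NA_character_, length(uniq))
    for (i in seq_along(uniq)) {
      if (is.na(can[i])) {
        ureasons[i] <- "bad_structure"
        next
      }
      comps <- comp_lists[[i]]
      ci <- info[match(comps, info$component), ]
      ci <- ci[ci$has_carbon, ]
      if (nrow(ci) == 0L) {
        ureasons[i] <- "no_organic_component"
        next
      }
      # drop salt/solvent components, but never the last fragment standing
      non_salt <- ci[!(ci$cansmi_ns %in% salt_list), ]
      if (nrow(non_salt) > 0L) {
        ci <- non_salt
      }
      ci <- ci[order(-ci$heavy_atoms, ci$cansmi_ns, method = "radix"), ]
      ukeys[i] <- ci$cansmi_ns[1]
    }
    idx <- match(smiles, uniq)
    keys <- ukeys[idx]
    reasons <- ureasons[idx]
  }
  empty <- is.na(smiles) | !nzchar(trimws(ifelse(is.na(smiles), "", smiles)))
  reasons[empty] <- "bad_structure"
  bad <- !is.na(reasons)
  attr(keys, "rejected") <- tibble::tibble(
    smiles_raw = smiles[bad], reason = reasons[bad]
  )
  keys
}

#' Aggregate activity records into standardized compounds
#'
#' Assigns every activity record's structure to a compound key so that salt
#' forms and stereoisomers of one parent pool their measurements. Keys
#' partition the accepted records: every `compound_ref` lands in exactly one
#' standardized compound.
#'
#' @param records unified activity-record tibble (see
#'   [read_activity_table()]).
#' @param salt_list canonical salt/solvent forms.
#' @return list with `compounds` (tibble: `compound_key`, `member_refs`
#'   list-column, `smiles_raw_examples` list-column of up to 3 originals),
#'   `records` (input records with a `compound_key` column, structure
#'   rejects removed), and `rejected` (tibble: `compound_ref`, `smiles_raw`,
#'   `reason`).
#' @export
aggregate_compounds <- function(records, salt_list = default_salt_list()) {
  keys <- standardize_structure(records$smiles_raw, salt_list = salt_list)
  ok <- !is.na(keys)
  rejected <- tibble::tibble(
    compound_ref = records$compound_ref[!ok],
    smiles_raw = records$smiles_raw[!ok],
    reason = attr(keys, "rejected")$reason[match(records$smiles_raw[!ok],
                                                 attr(keys, "rejected")$smiles_raw)]
  )
  rec <- records[ok, ]
  rec$compound_key <- keys[ok]
  compounds <- rec |>
    dplyr::group_by(.data$compound_key) |>
    dplyr::summarise(
      member_refs = list(sort(unique(.data$compound_ref))),
      smiles_raw_examples = list(utils::head(unique(.data$smiles_raw), 3L)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$compound_key)
  list(compounds = compounds, records = rec, rejected = rejected)
}
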