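# Independent brute-force oracles and small random-instance generators.
# These deliberately re-derive results with naive base-R loops, sharing
# only the structure-canonicalization primitive with the package.

# --- shared fixtures ------------------------------------------------------

.test_env <- new.env(parent = emptyenv())

# one moderately sized catalog reused across test files
test_catalog <- function() {
  if (is.null(.test_env$cat)) {
    .test_env$cat <- generate_catalog(n_compounds = 40, n_pk_targets = 15,
                                      n_nonpk_targets = 10, seed = 42)
  }
  .test_env$cat
}

catalog_records <- function(cat) {
  dir <- tempfile("cat_")
  paths <- write_catalog(cat, dir)
  ch <- read_activity_table(paths[["chembl"]], "chembl")
  bd <- read_activity_table(paths[["bindingdb"]], "bindingdb")
  dplyr::bind_rows(ch$records, bd$records)
}

# small random target table (no chemistry involved)
toy_targets <- function(n_pk = 5, n_nonpk = 4, n_at = 0) {
  tibble::tibble(
    target_id = c(sprintf("PK%02d", seq_len(n_pk)),
                  sprintf("NP%02d", seq_len(n_nonpk)),
                  if (n_at > 0) sprintf("AT%02d", seq_len(n_at)) else character(0)),
    uniprot = sprintf("U%05d", seq_len(n_pk + n_nonpk + n_at)),
    name = sprintf("target %d", seq_len(n_pk + n_nonpk + n_at)),
    is_pk = c(rep(TRUE, n_pk), rep(FALSE, n_nonpk + n_at)),
    kinase_group = c(rep("TK", n_pk), rep(NA_character_, n_nonpk + n_at)),
    class_l1 = c(rep("Enzyme", n_pk), rep("Membrane receptor", n_nonpk),
                 rep("Ion channel", n_at)),
    class_l2 = c(rep("Kinase", n_pk), rep("7tm1", n_nonpk),
                 rep(NA_character_, n_at)),
    is_antitarget = c(rep(FALSE, n_pk + n_nonpk), rep(TRUE, n_at))
  )
}

# random curated-interaction table against toy targets (no chemistry)
random_interactions <- function(seed, n_compounds = 25, n_pk = 8,
                                n_nonpk = 6) {
  set.seed(seed)
  targets <- toy_targets(n_pk, n_nonpk)
  rows <- list()
  for (i in seq_len(n_compounds)) {
    ids <- sample(targets$target_id, sample(2:6, 1))
    rows[[i]] <- tibble::tibble(
      compound_key = sprintf("CMP%03d", i),
      target_id = ids,
      uniprot = targets$uniprot[match(ids, targets$target_id)],
      is_pk = targets$is_pk[match(ids, targets$target_id)],
      ppot_final = round(runif(length(ids), 5, 9.5), 3),
      basis = "equilibrium",
      n_measurements = 1L
    )
  }
  list(interactions = dplyr::bind_rows(rows), targets = targets)
}

# random analysis-set profiles (targets T1..Tn, no chemistry)
random_profiles <- function(seed, n_compounds = 30, n_targets = 20) {
  set.seed(seed)
  t_ids <- sprintf("T%03d", seq_len(n_targets))
  pk_flag <- seq_len(n_targets) <= n_targets / 2
  rows <- lapply(seq_len(n_compounds), function(i) {
    pk <- sample(t_ids[pk_flag], sample(1:4, 1))
    np <- sample(t_ids[!pk_flag], sample(1:3, 1))
    tibble::tibble(compound_key = sprintf("CMP%03d", i),
                   pk_targets = list(sort(pk)),
                   nonpk_targets = list(sort(np)),
                   pk_pd = length(pk), nonpk_pd = length(np))
  })
  list(profiles = dplyr::bind_rows(rows),
       target_ids = t_ids, is_pk = pk_flag)
}

# --- network oracle: O(T^2 * C) pairwise intersection count ---------------

brute_force_edges <- function(profiles, min_shared = 2) {
  sets <- lapply(seq_len(nrow(profiles)), function(i) {
    unique(c(profiles$pk_targets[[i]], profiles$nonpk_targets[[i]]))
  })
  targets <- sort(unique(unlist(sets)))
  out <- list()
  k <- 0L
  for (i in seq_along(targets)) {
    for (j in seq_len(i - 1L)) {
      a <- targets[j]
      b <- targets[i]
      n_shared <- 0L
      for (s in sets) {
        if (a %in% s && b %in% s) n_shared <- n_shared + 1L
      }
      if (n_shared >= min_shared) {
        k <- k + 1L
        out[[k]] <- data.frame(target_a = min(a, b), target_b = max(a, b),
                               n_shared = n_shared,
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) {
    return(tibble::tibble(target_a = character(0), target_b = character(0),
                          n_shared = integer(0)))
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$target_a, res$target_b, method = "radix"), ]
  tibble::as_tibble(res)
}

# --- curation oracle: naive single-pass record walk -----------------------
# filter -> standardize -> pool by (compound, target, endpoint) ->
# average if consistent -> prioritize Ki/Kd -> max -> threshold

brute_force_curate <- function(records, targets, ppot_min = 5,
                               cutoff = 1.0) {
  ok <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (r$source == "chembl") {
      ok[i] <- identical(r$target_type, "SINGLE PROTEIN") &&
        identical(r$organism, "Homo sapiens") &&
        identical(r$assay_relationship, "D") &&
        isTRUE(r$confidence_score == 9) &&
        identical(r$relation, "=") && identical(r$units, "nM") &&
        r$measurement_type %in% c("IC50", "Ki", "Kd")
    } else {
      ok[i] <- identical(r$target_type, "SINGLE PROTEIN") &&
        identical(r$organism, "Homo sapiens") &&
        identical(r$relation, "=") && identical(r$units, "nM") &&
        r$measurement_type %in% c("IC50", "Ki", "Kd")
    }
  }
  rec <- records[ok, ]
  keys <- standardize_structure(rec$smiles_raw)
  rec <- rec[!is.na(keys), ]
  rec$compound_key <- keys[!is.na(keys)]

  tid <- rec$target_ref
  miss <- !(tid %in% targets$target_id)
  tid[miss] <- targets$target_id[match(rec$uniprot[miss], targets$uniprot)]
  rec <- rec[!is.na(tid), ]
  rec$target_id <- tid[!is.na(tid)]

  # contradicted pairs lose everything
  vocab <- c("inactive", "inconclusive", "not active")
  bad_pair <- unique(paste(
    rec$compound_key[tolower(trimws(ifelse(is.na(rec$activity_comment), "",
                                           rec$activity_comment))) %in% vocab],
    rec$target_id[tolower(trimws(ifelse(is.na(rec$activity_comment), "",
                                        rec$activity_comment))) %in% vocab]
  ))
  rec <- rec[!(paste(rec$compound_key, rec$target_id) %in% bad_pair), ]
  if (nrow(rec) == 0L) {
    return(tibble::tibble(compound_key = character(0),
                          target_id = character(0),
                          ppot_final = numeric(0), basis = character(0)))
  }
  rec$ppot <- 9 - log10(rec$value)
  rec$is_pk <- targets$is_pk[match(rec$target_id, targets$target_id)]

  out <- list()
  k <- 0L
  for (pair in unique(paste(rec$compound_key, rec$target_id, sep = "\r"))) {
    parts <- strsplit(pair, "\r", fixed = TRUE)[[1]]
    sub <- rec[rec$compound_key == parts[1] & rec$target_id == parts[2], ]
    avgs <- c()
    for (ep in c("IC50", "Ki", "Kd")) {
      v <- sub$ppot[sub$measurement_type == ep]
      if (length(v) == 0L) next
      if (sub$is_pk[1]) {
        if (max(v) - min(v) < cutoff) avgs[ep] <- mean(v)
      } else {
        if (sqrt(mean((v - mean(v))^2)) <= cutoff) avgs[ep] <- mean(v)
      }
    }
    eq <- avgs[names(avgs) %in% c("Ki", "Kd")]
    if (length(eq) > 0L) {
      final <- max(eq)
      basis <- "equilibrium"
    } else if ("IC50" %in% names(avgs)) {
      final <- avgs[["IC50"]]
      basis <- "ic50"
    } else {
      next
    }
    if (final >= ppot_min) {
      k <- k + 1L
      out[[k]] <- data.frame(compound_key = parts[1], target_id = parts[2],
                             ppot_final = final, basis = basis,
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    return(tibble::tibble(compound_key = character(0),
                          target_id = character(0),
                          ppot_final = numeric(0), basis = character(0)))
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$compound_key, res$target_id, method = "radix"), ]
  tibble::as_tibble(res)
}
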