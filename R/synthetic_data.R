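#' @title Synthetic activity data with planted ground truth
#' @description Generates raw ChEMBL-style and BindingDB-style activity
#'   tables, a target catalog and a ground-truth manifest with known
#'   promiscuity structure, so that every pipeline stage can be exercised
#'   and checked without database downloads. The generator emulates the
#'   features the curation rules exist for: salt/stereo variants of a
#'   parent structure, replicate measurements with controllable log-scale
#'   noise, contradictory "inactive" comments next to numbers, non-"="
#'   relations, non-human rows, interference-motif decoys and anti-target
#'   actives. Structures are combinatorial amide/ester scaffolds (no
#'   external structure source); interference decoys embed a quinone motif
#'   matching the shipped interference catalog. Noise is Gaussian on the
#'   pPot scale (log-normal assay error) and truncated so that planted
#'   consistent replicate groups provably satisfy the span/SD rules and
#'   stay above the activity threshold, while planted inconsistent groups
#'   provably violate both rules — the manifest therefore fully determines
#'   the expected output of every stage under the default configuration.
#' @name synthetic_data
NULL

.syn_chains <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CC(C)", "CC(C)C",
                 "CCN(C)", "CCO", "CCC(C)", "CC(N)", "CCC(N)", "CCCC(N)",
                 "CCOC", "CCCN(C)")
.syn_rings <- c("c1ccccc1", "c1ccncc1", "c1cccnc1", "c1ccc(C)cc1",
                "c1ccc(O)cc1", "c1ccc(N)cc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1",
                "C1CCCCC1", "C1CCNCC1", "c1ccc2ccccc2c1", "c1ccc(OC)cc1",
                "c1ccc(C(F)(F)F)cc1", "c1cnccn1", "c1ccc(CC)cc1", "C1CCOCC1")

# Deterministic pools of unique, standardizable parent structures.
# Decoys embed a para-quinone motif recognized by the shipped
# interference catalog.
# prefixes used to grow the pool combinatorially when more unique parents
# are needed than the base grid provides
.syn_prefixes <- c("", "CC(C)(C)", "C1CC1", "OCC(C)", "CN(C)CC", "COCC",
                   "CSCC", "OC(C)CC", "CC(C)OCC", "CN(CC)CC")

.syn_structures <- function(n_parents, n_decoys,
                            salt_list = default_salt_list()) {
  pool <- .pki_env[["synpool"]]
  if (is.null(pool)) {
    pool <- list(parents = character(0), parent_keys = character(0),
                 decoys = character(0), decoy_keys = character(0),
                 level = 0L)
  }
  while ((length(pool$parents) < n_parents ||
            length(pool$decoys) < n_decoys) &&
           pool$level < length(.syn_prefixes)) {
    pool$level <- pool$level + 1L
    prefix <- .syn_prefixes[pool$level]
    grid <- expand.grid(chain = .syn_chains, ring = .syn_rings,
                        form = c("C(=O)N", "NC(=O)", "OC(=O)"),
                        stringsAsFactors = FALSE)
    cand <- paste0(prefix, grid$chain, grid$form, grid$ring)
    keys <- standardize_structure(cand, salt_list = salt_list)
    ok <- !is.na(keys) & !duplicated(keys) & !(keys %in% pool$parent_keys)
    pool$parents <- c(pool$parents, cand[ok])
    pool$parent_keys <- c(pool$parent_keys, keys[ok])
    dgrid <- expand.grid(chain = .syn_chains, ring = c("", .syn_rings),
                         stringsAsFactors = FALSE)
    dcand <- paste0("O=C1C=CC(=O)C(=C1)N", prefix, dgrid$chain, dgrid$ring)
    dkeys <- standardize_structure(dcand, salt_list = salt_list)
    dok <- !is.na(dkeys) & !duplicated(dkeys) & !(dkeys %in% pool$decoy_keys)
    pool$decoys <- c(pool$decoys, dcand[dok])
    pool$decoy_keys <- c(pool$decoy_keys, dkeys[dok])
    .pki_env[["synpool"]] <- pool
  }
  if (length(pool$parents) < n_parents) {
    pki_abort("synthetic structure pool exhausted; reduce n_compounds",
              "pki_bad_config")
  }
  if (length(pool$decoys) < n_decoys) {
    pki_abort("synthetic decoy pool exhausted", "pki_bad_config")
  }
  list(parents = pool$parents[seq_len(n_parents)],
       parent_keys = pool$parent_keys[seq_len(n_parents)],
       decoys = pool$decoys[seq_len(max(n_decoys, 0L))],
       decoy_keys = pool$decoy_keys[seq_len(max(n_decoys, 0L))])
}

.syn_draw_degree <- function(weights, n_avail) {
  bins <- list(c(1, 1), c(2, 4), c(5, 9), c(10, 14))
  b <- sample.int(4L, 1L, prob = weights)
  lo <- bins[[b]][1]
  hi <- min(bins[[b]][2], n_avail)
  if (hi < lo) {
    lo <- hi
  }
  if (hi == lo) lo else sample(seq.int(lo, hi), 1L)
}

#' Generate a synthetic activity catalog with ground truth
#'
#' @param n_compounds number of parent compounds.
#' @param n_pk_targets,n_nonpk_targets,n_antitargets catalog sizes.
#' @param pk_pd_weights,nonpk_pd_weights sampling weights over the degree
#'   bins `[1], [2,4], [5,9], [10+]`; defaults emulate the observed shape
#'   of kinase-inhibitor promiscuity (single-target dominant, long tail).
#' @param replicate_noise_sd Gaussian replicate noise SD in log units.
#' @param fraction_contradicted fraction of compound-target pairs given an
#'   additional "inactive"-commented row.
#' @param fraction_inconsistent fraction of pairs whose replicate groups
#'   are planted to violate the span/SD consistency rules.
#' @param fraction_interference fraction of compounds built on the quinone
#'   decoy scaffold.
#' @param fraction_antitarget fraction of compounds given an extra
#'   interaction against an anti-target.
#' @param fraction_variants fraction of compounds also emitted as
#'   salt/stereo variants with distinct source compound IDs.
#' @param fraction_relation_violation,fraction_wrong_organism fractions of
#'   compounds given an extra record with a `">"` relation / a non-human
#'   organism (rejected by the confidence filter; they never change
#'   expected results).
#' @param bindingdb_fraction probability that a measurement row is emitted
#'   in the BindingDB dialect instead of the ChEMBL dialect.
#' @param max_replicates maximal replicate count per endpoint group.
#' @param ppot_range range of true pPot values.
#' @param submicromolar_fraction probability that a true pPot falls in the
#'   sub-micromolar stratum (> 6.2), so potency scans have signal.
#' @param seed RNG seed; the same seed reproduces byte-identical tables.
#' @param emit_tables set `FALSE` to return only the manifest (degree
#'   draws, flags, structures) without emitting the raw measurement rows;
#'   used for distribution-shape checks at large `n_compounds`.
#' @return list of class `pki_catalog` with `chembl`, `bindingdb` (activity
#'   tibbles in the two dialects), `target_table` (target-metadata tibble)
#'   and `manifest` (`pki_manifest`: `params`, `compounds`, `targets`,
#'   `interactions`).
#' @export
generate_catalog <- function(n_compounds = 200, n_pk_targets = 60,
                             n_nonpk_targets = 40, n_antitargets = 3,
                             pk_pd_weights = c(0.573, 0.221, 0.036, 0.170),
                             nonpk_pd_weights = c(0.783, 0.192, 0.020, 0.005),
                             replicate_noise_sd = 0.2,
                             fraction_contradicted = 0.05,
                             fraction_inconsistent = 0.05,
                             fraction_interference = 0.05,
                             fraction_antitarget = 0.05,
                             fraction_variants = 0.2,
                             fraction_relation_violation = 0.05,
                             fraction_wrong_organism = 0.05,
                             bindingdb_fraction = 0.3,
                             max_replicates = 3,
                             ppot_range = c(5.2, 9.5),
                             submicromolar_fraction = 0.6,
                             seed = 1, emit_tables = TRUE) {
  stopifnot(n_compounds >= 1, n_pk_targets >= 1, n_nonpk_targets >= 1)
  if (fraction_interference + fraction_antitarget > 1 ||
      fraction_contradicted + fraction_inconsistent > 1) {
    pki_abort("planted fractions combine to more than 1", "pki_bad_config")
  }
  pk_pd_weights <- pk_pd_weights / sum(pk_pd_weights)
  nonpk_pd_weights <- nonpk_pd_weights / sum(nonpk_pd_weights)

  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)

  n <- n_compounds
  k_int <- round(fraction_interference * n)
  k_at <- round(fraction_antitarget * n)
  k_var <- round(fraction_variants * n)
  k_rel <- round(fraction_relation_violation * n)
  k_org <- round(fraction_wrong_organism * n)

  structs <- .syn_structures(n, k_int)
  interference <- rep(FALSE, n)
  if (k_int > 0) {
    interference[sample.int(n, k_int)] <- TRUE
  }
  smiles <- structs$parents
  keys <- structs$parent_keys
  if (k_int > 0) {
    smiles[interference] <- structs$decoys[seq_len(k_int)]
    keys[interference] <- structs$decoy_keys[seq_len(k_int)]
  }
  antitarget_active <- rep(FALSE, n)
  if (k_at > 0) {
    pool <- which(!interference)
    antitarget_active[sample(pool, min(k_at, length(pool)))] <- TRUE
  }
  has_variants <- rep(FALSE, n)
  if (k_var > 0) {
    has_variants[sample.int(n, k_var)] <- TRUE
  }
  relation_violation <- rep(FALSE, n)
  if (k_rel > 0) {
    relation_violation[sample.int(n, k_rel)] <- TRUE
  }
  wrong_organism <- rep(FALSE, n)
  if (k_org > 0) {
    wrong_organism[sample.int(n, k_org)] <- TRUE
  }

  compound_id <- sprintf("CPD%04d", seq_len(n))
  variant_smiles <- vector("list", n)
  variant_refs <- vector("list", n)
  for (i in seq_len(n)) {
    if (!has_variants[i]) next
    vs <- paste0(smiles[i], ".Cl")
    vr <- paste0(compound_id[i], "A")
    if (grepl("C(N)", smiles[i], fixed = TRUE)) {
      vs <- c(vs, sub("C(N)", "[C@@H](N)", smiles[i], fixed = TRUE))
      vr <- c(vr, paste0(compound_id[i], "B"))
    }
    variant_smiles[[i]] <- vs
    variant_refs[[i]] <- vr
  }

  # target catalog
  pk_ids <- sprintf("PK%03d", seq_len(n_pk_targets))
  npk_ids <- sprintf("NPK%03d", seq_len(n_nonpk_targets))
  at_ids <- if (n_antitargets > 0) sprintf("AT%02d", seq_len(n_antitargets)) else character(0)
  cls_probs <- c("Enzyme" = 0.42, "Membrane receptor" = 0.21,
                 "Unclassified" = 0.10, "Epigenetic regulator" = 0.05,
                 "Ion channel" = 0.05, "Transcription factor" = 0.05,
                 "Transporter" = 0.04, "Secreted protein" = 0.04,
                 "Cytosolic other protein" = 0.02, "Other" = 0.02)
  npk_class <- sample(names(cls_probs), n_nonpk_targets, replace = TRUE,
                      prob = cls_probs)
  enz_l2 <- c("Reductase", "Hydrolase", "Protease", "Transferase",
              "Oxidoreductase", "Lyase", "Isomerase", "Phosphodiesterase",
              "Ligase")
  enz_probs <- c(0.28, 0.23, 0.14, 0.10, 0.08, 0.06, 0.05, 0.03, 0.03)
  npk_l2 <- rep(NA_character_, n_nonpk_targets)
  is_enz <- npk_class == "Enzyme"
  npk_l2[is_enz] <- sample(enz_l2, sum(is_enz), replace = TRUE, prob = enz_probs)
  is_mr <- npk_class == "Membrane receptor"
  npk_l2[is_mr] <- sample(c("7tm1", "7tm2"), sum(is_mr), replace = TRUE,
                          prob = c(0.98, 0.02))
  at_meta <- data.frame(
    name = c("hERG", "Cytochrome P450 3A4", "Serum albumin",
             "Cytochrome P450 2D6", "Cytochrome P450 2C9"),
    class = c("Ion channel", "Enzyme", "Secreted protein", "Enzyme", "Enzyme"),
    stringsAsFactors = FALSE
  )
  at_rows <- ((seq_len(max(n_antitargets, 0L)) - 1L) %% nrow(at_meta)) + 1L
  target_table <- tibble::tibble(
    target_id = c(pk_ids, npk_ids, at_ids),
    uniprot = c(sprintf("UPK%05d", seq_len(n_pk_targets)),
                sprintf("UNP%05d", seq_len(n_nonpk_targets)),
                if (n_antitargets > 0) sprintf("UAT%05d", seq_len(n_antitargets)) else character(0)),
    name = c(sprintf("Synthetic kinase %03d", seq_len(n_pk_targets)),
             sprintf("Synthetic non-kinase target %03d", seq_len(n_nonpk_targets)),
             if (n_antitargets > 0) at_meta$name[at_rows] else character(0)),
    is_pk = c(rep(TRUE, n_pk_targets), rep(FALSE, n_nonpk_targets),
              rep(FALSE, n_antitargets)),
    kinase_group = c(sample(kinase_groups(), n_pk_targets, replace = TRUE),
                     rep(NA_character_, n_nonpk_targets + n_antitargets)),
    class_l1 = c(rep("Enzyme", n_pk_targets), npk_class,
                 if (n_antitargets > 0) at_meta$class[at_rows] else character(0)),
    class_l2 = c(rep("Kinase", n_pk_targets), npk_l2,
                 rep(NA_character_, n_antitargets)),
    is_antitarget = c(rep(FALSE, n_pk_targets + n_nonpk_targets),
                      rep(TRUE, n_antitargets))
  )

  # planted interactions
  rows <- list()
  for (i in seq_len(n)) {
    pk_deg <- .syn_draw_degree(pk_pd_weights, n_pk_targets)
    npk_deg <- .syn_draw_degree(nonpk_pd_weights, n_nonpk_targets)
    tids <- c(sample(pk_ids, pk_deg), sample(npk_ids, npk_deg))
    ispk <- c(rep(TRUE, pk_deg), rep(FALSE, npk_deg))
    isat <- rep(FALSE, pk_deg + npk_deg)
    if (antitarget_active[i]) {
      tids <- c(tids, sample(at_ids, 1L))
      ispk <- c(ispk, FALSE)
      isat <- c(isat, TRUE)
    }
    m <- length(tids)
    strat <- runif(m) < submicromolar_fraction
    tp <- ifelse(strat,
                 runif(m, max(6.2, ppot_range[1]), ppot_range[2]),
                 runif(m, ppot_range[1], min(6.2, ppot_range[2])))
    n_ep <- ifelse(runif(m) < 0.7, 1L, 2L)
    eps <- lapply(seq_len(m), function(j) sample(c("IC50", "Ki", "Kd"), n_ep[j]))
    reps <- lapply(seq_len(m), function(j) {
      sample.int(max_replicates, n_ep[j], replace = TRUE)
    })
    rows[[i]] <- tibble::tibble(
      compound_id = compound_id[i], target_id = tids, is_pk = ispk,
      is_antitarget = isat, true_ppot = tp, endpoints = eps,
      n_replicates = reps
    )
  }
  interactions <- dplyr::bind_rows(rows)
  np <- nrow(interactions)
  interactions$contradicted <- FALSE
  interactions$consistent <- TRUE
  # anti-target hits stay clean so flagged compounds are always removable
  eligible <- which(!interactions$is_antitarget)
  k_con <- round(fraction_contradicted * length(eligible))
  k_inc <- round(fraction_inconsistent * length(eligible))
  ord <- sample(eligible)
  if (k_con > 0) {
    interactions$contradicted[ord[seq_len(k_con)]] <- TRUE
  }
  if (k_inc > 0) {
    inc_idx <- ord[seq.int(k_con + 1L, min(length(eligible), k_con + k_inc))]
    interactions$consistent[inc_idx] <- FALSE
    # inconsistency needs at least two replicates in every group
    interactions$n_replicates[inc_idx] <- lapply(
      interactions$n_replicates[inc_idx], function(v) pmax(v, 2L))
  }

  compounds <- tibble::tibble(
    compound_id = compound_id, parent_smiles = smiles, compound_key = keys,
    variant_smiles = variant_smiles, variant_refs = variant_refs,
    interference = interference, antitarget_active = antitarget_active,
    relation_violation = relation_violation, wrong_organism = wrong_organism
  )
  manifest <- structure(list(
    params = list(
      n_compounds = n_compounds, n_pk_targets = n_pk_targets,
      n_nonpk_targets = n_nonpk_targets, n_antitargets = n_antitargets,
      pk_pd_weights = pk_pd_weights, nonpk_pd_weights = nonpk_pd_weights,
      replicate_noise_sd = replicate_noise_sd,
      fraction_contradicted = fraction_contradicted,
      fraction_inconsistent = fraction_inconsistent,
      fraction_interference = fraction_interference,
      fraction_antitarget = fraction_antitarget,
      fraction_variants = fraction_variants,
      fraction_relation_violation = fraction_relation_violation,
      fraction_wrong_organism = fraction_wrong_organism,
      bindingdb_fraction = bindingdb_fraction,
      max_replicates = max_replicates, ppot_range = ppot_range,
      submicromolar_fraction = submicromolar_fraction, seed = seed
    ),
    compounds = compounds, targets = target_table,
    interactions = interactions
  ), class = "pki_manifest")

  tabs <- if (emit_tables) {
    .emit_tables(manifest, mode = "default", noise_sd = replicate_noise_sd)
  } else {
    list(chembl = NULL, bindingdb = NULL)
  }
  structure(list(chembl = tabs$chembl, bindingdb = tabs$bindingdb,
                 target_table = target_table, manifest = manifest),
            class = "pki_catalog")
}

# Emit raw activity tables from a manifest.
# mode "default": truncated/centered noise honoring consistency flags;
# mode "exact": no noise; mode "raw": uncentered Gaussian noise (sd
# noise_sd), consistency flags ignored.
.emit_tables <- function(manifest, mode = "default", noise_sd = 0.2) {
  cmp <- manifest$compounds
  tgt <- manifest$targets
  ia <- manifest$interactions
  bdb_frac <- manifest$params$bindingdb_fraction

  forms_smiles <- lapply(seq_len(nrow(cmp)), function(i) {
    c(cmp$parent_smiles[i], cmp$variant_smiles[[i]])
  })
  forms_refs <- lapply(seq_len(nrow(cmp)), function(i) {
    c(cmp$compound_id[i], cmp$variant_refs[[i]])
  })
  names(forms_smiles) <- names(forms_refs) <- cmp$compound_id
  up <- setNames(tgt$uniprot, tgt$target_id)

  out <- vector("list", nrow(ia) + nrow(cmp))
  oi <- 0L
  emit <- function(df) {
    oi <<- oi + 1L
    out[[oi]] <<- df
  }
  mk_rows <- function(cid, tid, ep, ppots, relation = "=",
                      organism = "Homo sapiens", comment = NA_character_,
                      force_chembl = FALSE) {
    nr <- length(ppots)
    fi <- sample.int(length(forms_refs[[cid]]), nr, replace = TRUE)
    src_bdb <- if (force_chembl) rep(FALSE, nr) else runif(nr) < bdb_frac
    tibble::tibble(
      source = ifelse(src_bdb, "bindingdb", "chembl"),
      compound_ref = forms_refs[[cid]][fi],
      smiles = forms_smiles[[cid]][fi],
      target_id = tid, uniprot = unname(up[tid]),
      organism = organism, measurement_type = ep, relation = relation,
      value = signif(10^(9 - ppots), 10), units = "nM",
      activity_comment = comment
    )
  }

  for (r in seq_len(nrow(ia))) {
    cid <- ia$compound_id[r]
    tid <- ia$target_id[r]
    tp <- ia$true_ppot[r]
    eps <- ia$endpoints[[r]]
    reps <- ia$n_replicates[[r]]
    for (j in seq_along(eps)) {
      nr <- reps[j]
      ppots <- if (mode == "exact") {
        rep(tp, nr)
      } else if (mode == "raw") {
        tp + rnorm(nr, 0, noise_sd)
      } else if (!ia$consistent[r]) {
        tp + c(-1.3, 1.3, rep(0, max(nr - 2L, 0L)))[seq_len(nr)]
      } else {
        offset <- min(max(rnorm(1, 0, noise_sd / 2), -0.15), 0.15)
        dev <- pmin(pmax(rnorm(nr, 0, noise_sd), -0.45), 0.45)
        if (nr > 1L) dev <- dev - mean(dev) else dev <- 0
        tp + offset + dev
      }
      emit(mk_rows(cid, tid, eps[j], ppots))
    }
    if (isTRUE(ia$contradicted[r]) && mode != "raw") {
      emit(mk_rows(cid, tid, ia$endpoints[[r]][1], tp,
                   comment = "inactive", force_chembl = TRUE))
    }
  }
  # confidence-filter decoy rows (never affect expected outputs)
  if (mode == "default") {
    for (i in which(cmp$relation_violation)) {
      first <- which(ia$compound_id == cmp$compound_id[i])[1]
      emit(mk_rows(cmp$compound_id[i], ia$target_id[first],
                   ia$endpoints[[first]][1], ia$true_ppot[first] - 1,
                   relation = ">", force_chembl = TRUE))
    }
    for (i in which(cmp$wrong_organism)) {
      first <- which(ia$compound_id == cmp$compound_id[i])[1]
      emit(mk_rows(cmp$compound_id[i], ia$target_id[first],
                   ia$endpoints[[first]][1], ia$true_ppot[first],
                   organism = "Rattus norvegicus"))
    }
  }
  long <- dplyr::bind_rows(out[seq_len(oi)])

  ch <- long[long$source == "chembl", ]
  chembl <- tibble::tibble(
    compound_id = ch$compound_ref, smiles = ch$smiles,
    target_id = ch$target_id, uniprot = ch$uniprot, organism = ch$organism,
    target_type = "SINGLE PROTEIN", assay_relationship = "D",
    confidence_score = 9L, standard_type = ch$measurement_type,
    standard_relation = ch$relation, standard_value = ch$value,
    standard_units = ch$units, activity_comment = ch$activity_comment
  )
  bd <- long[long$source == "bindingdb", ]
  bindingdb <- tibble::tibble(
    compound_id = bd$compound_ref, smiles = bd$smiles,
    target_id = paste0("chain:", bd$uniprot), uniprot = bd$uniprot,
    organism = bd$organism, n_chains = 1L,
    measurement_type = bd$measurement_type, relation = bd$relation,
    value = bd$value, units = bd$units,
    activity_comment = bd$activity_comment
  )
  list(chembl = chembl, bindingdb = bindingdb)
}

#' Expected analysis-set profiles implied by a manifest
#'
#' Applies the planted flags: a compound survives unless it is an
#' interference decoy or anti-target active; an interaction survives iff
#' its replicate groups are consistent, the pair is not contradicted and
#' the target is not an anti-target. Compounds with at least one surviving
#' kinase and one surviving non-kinase interaction form the expected
#' analysis set.
#'
#' @param manifest `pki_manifest`.
#' @return tibble with `compound_id`, `compound_key`, `pk_pd`, `nonpk_pd`,
#'   `pk_targets`, `nonpk_targets` (list-columns).
#' @export
manifest_expected_profiles <- function(manifest) {
  cmp <- manifest$compounds
  ia <- manifest$interactions
  ok_cmp <- cmp$compound_id[!cmp$interference & !cmp$antitarget_active]
  keep <- ia$consistent & !ia$contradicted & !ia$is_antitarget &
    ia$compound_id %in% ok_cmp
  ia <- ia[keep, ]
  prof <- ia |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      pk_targets = list(sort(unique(.data$target_id[.data$is_pk]))),
      nonpk_targets = list(sort(unique(.data$target_id[!.data$is_pk]))),
      .groups = "drop"
    ) |>
    dplyr::mutate(pk_pd = lengths(.data$pk_targets),
                  nonpk_pd = lengths(.data$nonpk_targets)) |>
    dplyr::filter(.data$pk_pd >= 1L, .data$nonpk_pd >= 1L)
  prof$compound_key <- cmp$compound_key[match(prof$compound_id, cmp$compound_id)]
  prof[, c("compound_id", "compound_key", "pk_pd", "nonpk_pd",
           "pk_targets", "nonpk_targets")]
}

#' Regenerate stress-scenario tables from a manifest
#'
#' `all_consistent` clears every planted contradiction and inconsistency;
#' `heavy_noise` redraws replicate values with untruncated Gaussian noise
#' (default SD 1.5) so many groups violate the consistency rules;
#' `threshold_edge` replaces all true potencies with values cycling through
#' pPot 4.99 / 5.00 / 5.01 emitted noise-free as single Ki measurements, so
#' exactly the values at or above 5.00 survive the activity threshold.
#'
#' @param manifest `pki_manifest` from [generate_catalog()].
#' @param scenario `"all_consistent"`, `"heavy_noise"` or
#'   `"threshold_edge"`.
#' @param noise_sd heavy-noise SD in log units.
#' @return list of class `pki_catalog` (as [generate_catalog()]) with the
#'   scenario-adjusted manifest.
#' @export
perturb_manifest <- function(manifest,
                             scenario = c("all_consistent", "heavy_noise",
                                          "threshold_edge"),
                             noise_sd = 1.5) {
  scenario <- match.arg(scenario)
  m <- manifest
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(m$params$seed + 10000L)

  if (scenario == "all_consistent") {
    m$interactions$consistent <- TRUE
    m$interactions$contradicted <- FALSE
    tabs <- .emit_tables(m, mode = "default",
                         noise_sd = m$params$replicate_noise_sd)
  } else if (scenario == "heavy_noise") {
    tabs <- .emit_tables(m, mode = "raw", noise_sd = noise_sd)
  } else {
    m$interactions$consistent <- TRUE
    m$interactions$contradicted <- FALSE
    m$interactions$true_ppot <- rep(c(4.99, 5.00, 5.01),
                                    length.out = nrow(m$interactions))
    m$interactions$endpoints <- rep(list("Ki"), nrow(m$interactions))
    m$interactions$n_replicates <- rep(list(1L), nrow(m$interactions))
    tabs <- .emit_tables(m, mode = "exact")
  }
  structure(list(chembl = tabs$chembl, bindingdb = tabs$bindingdb,
                 target_table = m$targets, manifest = m),
            class = "pki_catalog")
}

#' Write a synthetic catalog's raw tables to a directory
#'
#' @param catalog `pki_catalog` from [generate_catalog()].
#' @param dir output directory (created if missing).
#' @return named character vector of the three written paths.
#' @export
write_catalog <- function(catalog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    chembl = file.path(dir, "chembl_activities.tsv"),
    bindingdb = file.path(dir, "bindingdb_activities.tsv"),
    targets = file.path(dir, "targets.tsv")
  )
  write_table(catalog$chembl, paths["chembl"])
  write_table(catalog$bindingdb, paths["bindingdb"])
  write_table(catalog$target_table, paths["targets"])
  paths
}
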