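test_that("the same seed regenerates byte-identical tables", {
  a <- generate_catalog(n_compounds = 20, n_pk_targets = 8,
                        n_nonpk_targets = 6, seed = 1)
  b <- generate_catalog(n_compounds = 20, n_pk_targets = 8,
                        n_nonpk_targets = 6, seed = 1)
  expect_identical(a$chembl, b$chembl)
  expect_identical(a$bindingdb, b$bindingdb)
  expect_identical(a$target_table, b$target_table)
  d1 <- tempfile()
  d2 <- tempfile()
  p1 <- write_catalog(a, d1)
  p2 <- write_catalog(b, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  # a different seed changes the data
  c_ <- generate_catalog(n_compounds = 20, n_pk_targets = 8,
                         n_nonpk_targets = 6, seed = 2)
  expect_false(identical(a$chembl, c_$chembl))
})

test_that("zero contradiction fraction yields an empty dropped-pair list", {
  cat0 <- generate_catalog(n_compounds = 15, n_pk_targets = 8,
                           n_nonpk_targets = 6, fraction_contradicted = 0,
                           seed = 3)
  recs <- catalog_records(cat0)
  cur <- curate_interactions(recs, cat0$target_table)
  expect_equal(nrow(cur$discards$contradicted_pairs), 0L)
})

test_that("infeasible planted fractions are fatal", {
  expect_error(generate_catalog(n_compounds = 10,
                                fraction_interference = 0.7,
                                fraction_antitarget = 0.6, seed = 1),
               class = "pki_bad_config")
})

test_that("the manifest predicts contradicted and inconsistent pairs exactly", {
  cat <- test_catalog()
  recs <- catalog_records(cat)
  cur <- curate_interactions(recs, cat$target_table)
  man_ia <- cat$manifest$interactions
  man_cmp <- cat$manifest$compounds
  key_of <- function(cid) man_cmp$compound_key[match(cid, man_cmp$compound_id)]

  planted_con <- man_ia[man_ia$contradicted, ]
  expect_setequal(paste(cur$discards$contradicted_pairs$compound_key,
                        cur$discards$contradicted_pairs$target_id),
                  paste(key_of(planted_con$compound_id),
                        planted_con$target_id))

  planted_inc <- man_ia[!man_ia$consistent & !man_ia$contradicted, ]
  expect_setequal(unique(paste(cur$discards$inconsistent_groups$compound_key,
                               cur$discards$inconsistent_groups$target_id)),
                  paste(key_of(planted_inc$compound_id),
                        planted_inc$target_id))
})

test_that("the all_consistent scenario empties the curation discard ledger", {
  cat <- test_catalog()
  pert <- perturb_manifest(cat$manifest, "all_consistent")
  recs <- catalog_records(pert)
  cur <- curate_interactions(recs, pert$target_table)
  expect_equal(nrow(cur$discards$contradicted_pairs), 0L)
  expect_equal(nrow(cur$discards$inconsistent_groups), 0L)
  expect_equal(nrow(cur$discards$subthreshold_pairs), 0L)
})

test_that("the threshold_edge scenario retains exactly the pairs at pPot >= 5", {
  cat <- test_catalog()
  pert <- perturb_manifest(cat$manifest, "threshold_edge")
  recs <- catalog_records(pert)
  cur <- curate_interactions(recs, pert$target_table)
  man_ia <- pert$manifest$interactions
  man_cmp <- pert$manifest$compounds
  key_of <- function(cid) man_cmp$compound_key[match(cid, man_cmp$compound_id)]
  expected <- man_ia[man_ia$true_ppot >= 5.0, ]
  expect_setequal(paste(cur$interactions$compound_key,
                        cur$interactions$target_id),
                  paste(key_of(expected$compound_id), expected$target_id))
  expect_true(all(cur$interactions$ppot_final >= 5.0))
  dropped <- man_ia[man_ia$true_ppot < 5.0, ]
  expect_equal(nrow(cur$discards$subthreshold_pairs), nrow(dropped))
})

test_that("heavy noise discards match a brute-force span/SD recount", {
  cat <- generate_catalog(n_compounds = 25, n_pk_targets = 10,
                          n_nonpk_targets = 8, fraction_contradicted = 0,
                          fraction_interference = 0, fraction_antitarget = 0,
                          fraction_variants = 0, seed = 9)
  pert <- perturb_manifest(cat$manifest, "heavy_noise", noise_sd = 1.5)
  recs <- catalog_records(pert)
  cur <- curate_interactions(recs, pert$target_table)
  # recount discarded groups naively from the raw records
  keys <- standardize_structure(recs$smiles_raw)
  recs$compound_key <- keys
  tid <- recs$target_ref
  miss <- !(tid %in% pert$target_table$target_id)
  tid[miss] <- pert$target_table$target_id[
    match(recs$uniprot[miss], pert$target_table$uniprot)]
  recs$target_id <- tid
  recs$ppot <- 9 - log10(recs$value)
  recs$is_pk <- pert$target_table$is_pk[match(tid, pert$target_table$target_id)]
  n_bad <- 0L
  grp_id <- paste(recs$compound_key, recs$target_id, recs$measurement_type)
  for (g in unique(grp_id)) {
    v <- recs$ppot[grp_id == g]
    pk <- recs$is_pk[grp_id == g][1]
    bad <- if (pk) (max(v) - min(v)) >= 1 else pop_sd(v) > 1
    n_bad <- n_bad + as.integer(bad)
  }
  expect_equal(nrow(cur$discards$inconsistent_groups), n_bad)
  expect_gt(n_bad, 0L)
})

test_that("unknown perturbation scenarios are fatal", {
  cat <- test_catalog()
  expect_error(perturb_manifest(cat$manifest, "nonsense"))
})

test_that("generated degree frequencies follow the requested bin weights", {
  w <- c(0.573, 0.221, 0.036, 0.170)
  cat <- generate_catalog(n_compounds = 2000, n_pk_targets = 60,
                          n_nonpk_targets = 40, pk_pd_weights = w,
                          seed = 4, emit_tables = FALSE)
  deg <- vapply(split(cat$manifest$interactions$is_pk,
                      cat$manifest$interactions$compound_id), sum, 0L)
  bins <- c(sum(deg == 1), sum(deg >= 2 & deg <= 4),
            sum(deg >= 5 & deg <= 9), sum(deg >= 10))
  p <- stats::chisq.test(bins, p = w)$p.value
  expect_gt(p, 0.001)
})
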