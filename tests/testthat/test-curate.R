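make_records <- function(n, ...) {
  defaults <- list(
    source = "chembl", compound_ref = sprintf("C%d", seq_len(n)),
    smiles_raw = "CCO", target_ref = "T1", uniprot = "P1",
    organism = "Homo sapiens", target_type = "SINGLE PROTEIN",
    assay_relationship = "D", confidence_score = 9L,
    measurement_type = "IC50", relation = "=", value = 100,
    units = "nM", activity_comment = NA_character_
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(tibble::tibble, args)
}

test_that("pPot conversion matches the 10 uM = pPot 5 anchor", {
  expect_equal(to_ppot(10000), 5.0)
  expect_equal(to_ppot(1), 9.0)
  expect_equal(to_ppot(50), 7.30103, tolerance = 1e-6)
  expect_error(to_ppot(100, units = "uM"), class = "pki_unit_mismatch")
  expect_error(to_ppot(-1), class = "pki_bad_value")
  expect_error(to_ppot(0), class = "pki_bad_value")
})

test_that("confidence rules reject with the first failed rule's name", {
  rec <- make_records(6)
  rec$relation[1] <- ">"
  rec$confidence_score[2] <- 8L
  rec$organism[3] <- "Rattus norvegicus"
  rec$target_type[4] <- "PROTEIN FAMILY"
  rec$assay_relationship[5] <- "H"
  res <- filter_high_confidence(rec)
  expect_equal(nrow(res$accepted), 1L)
  expect_equal(res$rejected$reason,
               c("relation", "confidence", "organism", "target_type",
                 "assay_relationship"))
  # BindingDB dialect: no confidence/relationship requirement
  bdb <- make_records(2, source = "bindingdb",
                      assay_relationship = NA_character_,
                      confidence_score = NA_integer_)
  bdb$relation[2] <- ">"
  res2 <- filter_high_confidence(bdb)
  expect_equal(nrow(res2$accepted), 1L)
  expect_equal(res2$rejected$reason, "relation")
})

test_that("planted rule violations are all caught on synthetic data", {
  cat <- test_catalog()
  recs <- catalog_records(cat)
  res <- filter_high_confidence(recs)
  man <- cat$manifest$compounds
  # exactly the planted relation/organism decoy rows fail
  expect_equal(sum(res$rejected$reason == "relation"),
               sum(man$relation_violation))
  expect_equal(sum(res$rejected$reason == "organism"),
               sum(man$wrong_organism))
  expect_equal(nrow(res$accepted) + nrow(res$rejected), nrow(recs))
})

test_that("a pair with any contradictory comment loses all its records", {
  rec <- make_records(3)
  rec$compound_ref <- "C1"
  rec$compound_key <- "KEY1"
  rec$target_id <- c("T1", "T1", "T2")
  rec$activity_comment[2] <- "Inactive"
  res <- drop_contradicted_pairs(rec)
  expect_equal(nrow(res$records), 1L)
  expect_equal(res$records$target_id, "T2")
  expect_equal(res$dropped_pairs,
               tibble::tibble(compound_key = "KEY1", target_id = "T1"))
  # numeric-only pairs are untouched
  clean <- make_records(2)
  clean$compound_key <- "KEY1"
  clean$target_id <- "T1"
  expect_equal(nrow(drop_contradicted_pairs(clean)$records), 2L)
})

test_that("replicate pooling honors span and SD rules with their boundaries", {
  expect_equal(pool_and_average(6.5, "span")$value, 6.5)
  expect_equal(pool_and_average(6.5, "sd")$value, 6.5)
  expect_equal(pool_and_average(c(6.1, 6.3, 6.2), "span")$value, 6.2)
  # span of exactly one log unit is not "the same order of magnitude"
  span1 <- pool_and_average(c(5.5, 6.5), "span")
  expect_true(span1$discarded)
  expect_equal(span1$reason, "inconsistent_span")
  expect_false(pool_and_average(c(5.51, 6.5), "span")$discarded)
  # population SD boundary 1.0 is retained, above it discarded
  expect_false(pool_and_average(c(4.0, 6.0), "sd")$discarded)
  expect_equal(pop_sd(c(4.0, 6.0)), 1.0)
  sd_bad <- pool_and_average(c(4.0, 6.5), "sd")
  expect_true(sd_bad$discarded)
  expect_equal(sd_bad$reason, "inconsistent_sd")
})

test_that("equilibrium constants beat IC50 and the highest average wins", {
  g <- tibble::tibble(measurement_type = c("Ki", "IC50"),
                      avg = c(7.0, 8.5), n = c(2L, 3L))
  r <- resolve_final_annotation(g)
  expect_equal(r$ppot_final, 7.0)
  expect_equal(r$basis, "equilibrium")

  g2 <- tibble::tibble(measurement_type = c("Ki", "Kd"),
                       avg = c(6.0, 7.0), n = c(1L, 1L))
  expect_equal(resolve_final_annotation(g2)$ppot_final, 7.0)

  g3 <- tibble::tibble(measurement_type = "IC50", avg = 6.5, n = 2L)
  r3 <- resolve_final_annotation(g3)
  expect_equal(r3$ppot_final, 6.5)
  expect_equal(r3$basis, "ic50")

  expect_null(resolve_final_annotation(g3[0, ]))
})

test_that("the activity threshold is boundary-inclusive", {
  ia <- tibble::tibble(compound_key = c("A", "B"), target_id = "T",
                       ppot_final = c(5.0, 4.9))
  kept <- apply_activity_threshold(ia)
  expect_equal(kept$compound_key, "A")
  rec <- make_records(2, value = c(10000, 12000), measurement_type = "Ki",
                      target_ref = "PK01")
  cur <- curate_interactions(rec, toy_targets())
  # mean pPot of 10000 and 12000 nM sits just below 5: dropped
  expect_equal(nrow(cur$interactions), 0L)
  expect_equal(nrow(cur$discards$subthreshold_pairs), 1L)
})

test_that("curation is invariant under record permutation", {
  cat <- test_catalog()
  recs <- catalog_records(cat)
  targets <- cat$target_table
  a <- curate_interactions(recs, targets)
  set.seed(1)
  b <- curate_interactions(recs[sample.int(nrow(recs)), ], targets)
  expect_equal(a$interactions, b$interactions)
})

test_that("raising the threshold never adds interactions or degree", {
  cat <- test_catalog()
  recs <- catalog_records(cat)
  targets <- cat$target_table
  lo <- curate_interactions(recs, targets, ppot_min = 5)
  hi <- curate_interactions(recs, targets, ppot_min = 8)
  expect_lte(nrow(hi$interactions), nrow(lo$interactions))
  p_lo <- build_profiles(lo$interactions, targets)
  p_hi <- build_profiles(hi$interactions, targets)
  shared <- intersect(p_lo$compound_key, p_hi$compound_key)
  expect_true(all(p_hi$pk_pd[match(shared, p_hi$compound_key)] <=
                    p_lo$pk_pd[match(shared, p_lo$compound_key)]))
})

test_that("staged curation equals the naive brute-force oracle", {
  cat <- test_catalog()
  recs <- catalog_records(cat)
  targets <- cat$target_table
  got <- curate_interactions(recs, targets)$interactions
  want <- brute_force_curate(recs, targets)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$compound_key, want$compound_key)
  expect_equal(got$target_id, want$target_id)
  expect_equal(got$ppot_final, want$ppot_final, tolerance = 1e-12)
  expect_equal(got$basis, want$basis)
})
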