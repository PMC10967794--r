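toy_interactions <- function() {
  # c1: PK {A,B}, non-PK {X}; c2: PK {A}, non-PK {X,Y}; c3: PK only
  tibble::tibble(
    compound_key = c("c1", "c1", "c1", "c2", "c2", "c2", "c3"),
    target_id = c("PK01", "PK02", "NP01", "PK01", "NP01", "NP02", "PK02"),
    uniprot = NA_character_,
    is_pk = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    ppot_final = c(8, 7, 6, 5.5, 5.5, 7.5, 9),
    basis = "equilibrium", n_measurements = 1L
  )
}

test_that("profiles count distinct targets and exclude single-domain compounds", {
  targets <- toy_targets()
  prof <- build_profiles(toy_interactions(), targets)
  expect_equal(prof$compound_key, c("c1", "c2"))
  expect_equal(prof$pk_pd, c(2L, 1L))
  expect_equal(prof$nonpk_pd, c(1L, 2L))
  expect_false("c3" %in% prof$compound_key)
  bad <- toy_interactions()
  bad$target_id[1] <- "MISSING"
  expect_error(build_profiles(bad, targets), regexp = "MISSING",
               class = "pki_unknown_target")
})

test_that("degree binning reproduces printed-report percentages", {
  profiles <- tibble::tibble(
    compound_key = sprintf("c%03d", 1:447),
    pk_pd = c(rep(1L, 256), rep(3L, 99), rep(6L, 16), rep(12L, 76)),
    nonpk_pd = c(rep(1L, 350), rep(2L, 86), rep(7L, 8), rep(11L, 3))
  )
  pk <- bin_distribution(profiles, "pk")
  expect_equal(pk$count, c(256L, 99L, 16L, 76L))
  expect_equal(pk$percentage, c(57.3, 22.1, 3.6, 17.0))
  npk <- bin_distribution(profiles, "nonpk")
  expect_equal(npk$percentage[1:2], c(78.3, 19.2))
  expect_equal(sum(pk$count), 447L)
  expect_lt(abs(sum(pk$percentage) - 100), 0.1 + 1e-9)
})

test_that("a uniform toy set lands entirely in the first bin", {
  profiles <- tibble::tibble(compound_key = sprintf("c%d", 1:10),
                             pk_pd = rep(1L, 10), nonpk_pd = rep(1L, 10))
  d <- bin_distribution(profiles, "pk")
  expect_equal(d$count, c(10L, 0L, 0L, 0L))
  expect_equal(d$percentage, c(100.0, 0, 0, 0))
})

test_that("overlapping or gapped bins are fatal", {
  profiles <- tibble::tibble(compound_key = "c", pk_pd = 1L, nonpk_pd = 1L)
  expect_error(
    bin_distribution(profiles, "pk",
                     bins = list(a = c(1, 3), b = c(3, Inf))),
    class = "pki_bad_bins")
  expect_error(
    bin_distribution(profiles, "pk",
                     bins = list(a = c(1, 2), b = c(5, Inf))),
    class = "pki_bad_bins")
  expect_error(
    bin_distribution(profiles, "pk", bins = list(a = c(1, 5), b = c(6, 9))),
    class = "pki_bad_bins")
})

test_that("target ranking counts shared inhibitors and counterpart unions", {
  targets <- toy_targets()
  prof <- build_profiles(toy_interactions(), targets)
  pk_rank <- rank_targets_by_shared_inhibitors(prof, "pk", k = 10)
  a <- pk_rank[pk_rank$target_id == "PK01", ]
  expect_equal(a$n_shared_pkis, 2L)
  expect_equal(a$n_counterpart_targets, 2L)  # union {NP01, NP02}
  b <- pk_rank[pk_rank$target_id == "PK02", ]
  expect_equal(b$n_shared_pkis, 1L)
  expect_equal(b$n_counterpart_targets, 1L)
  np_rank <- rank_targets_by_shared_inhibitors(prof, "nonpk", k = 10)
  x <- np_rank[np_rank$target_id == "NP01", ]
  expect_equal(x$n_shared_pkis, 2L)
  expect_equal(x$n_counterpart_targets, 2L)  # union {PK01, PK02}
})

test_that("compound ranking sorts by non-kinase degree with documented ties", {
  prof <- tibble::tibble(
    compound_key = c("c1", "c2", "c3"),
    pk_targets = list("PK01", c("PK01", "PK02"), "PK01"),
    nonpk_targets = list(c("NP01", "NP02", "NP03"), c("NP01", "NP02"),
                         c("NP01", "NP02")),
    pk_pd = c(1L, 2L, 1L), nonpk_pd = c(3L, 2L, 2L)
  )
  r <- rank_compounds_by_nonpk_targets(prof, k = 10)
  expect_equal(r$compound_key, c("c1", "c2", "c3"))
  expect_equal(rank_compounds_by_nonpk_targets(prof, k = 2)$compound_key,
               c("c1", "c2"))
})

test_that("rankings match a brute-force recount on synthetic profiles", {
  rp <- random_profiles(101)
  got <- rank_targets_by_shared_inhibitors(rp$profiles, "pk", k = Inf)
  for (i in seq_len(nrow(got))) {
    tid <- got$target_id[i]
    hit <- vapply(seq_len(nrow(rp$profiles)), function(j) {
      tid %in% rp$profiles$pk_targets[[j]]
    }, TRUE)
    expect_equal(got$n_shared_pkis[i], sum(hit))
    expect_equal(got$n_counterpart_targets[i],
                 length(unique(unlist(rp$profiles$nonpk_targets[hit]))))
  }
})

test_that("the potency scan drops targets as thresholds rise", {
  targets <- toy_targets()
  ia <- toy_interactions()
  scan <- potency_scan(ia, targets, thresholds = c(5, 6, 7, 8))
  # NP01's best value is 6.0 (c1): present at 5 and 6, absent at 7
  expect_equal(scan$unique_nonpk_targets, c(2L, 2L, 1L, 0L))
  expect_equal(scan$unique_pk_targets, c(2L, 2L, 2L, 1L))
  # at the base threshold the scan equals the profile target unions
  prof <- build_profiles(ia, targets)
  expect_equal(scan$unique_pk_targets[1],
               length(unique(unlist(prof$pk_targets))))
  expect_equal(scan$unique_nonpk_targets[1],
               length(unique(unlist(prof$nonpk_targets))))
})

test_that("scan counts are monotone and match brute force across seeds", {
  for (seed in 1:50) {
    ri <- random_interactions(seed)
    scan <- potency_scan(ri$interactions, ri$targets)
    expect_false(is.unsorted(-scan$unique_pk_targets))
    expect_false(is.unsorted(-scan$unique_nonpk_targets))
  }
  # brute-force recount on a few instances
  for (seed in c(3, 17)) {
    ri <- random_interactions(seed)
    scan <- potency_scan(ri$interactions, ri$targets)
    prof <- build_profiles(ri$interactions, ri$targets)
    pool <- ri$interactions[ri$interactions$compound_key %in%
                              prof$compound_key, ]
    for (r in seq_len(nrow(scan))) {
      t <- scan$ppot_threshold[r]
      sub <- pool[pool$ppot_final >= t, ]
      expect_equal(scan$unique_pk_targets[r],
                   length(unique(sub$target_id[sub$is_pk])))
      expect_equal(scan$unique_nonpk_targets[r],
                   length(unique(sub$target_id[!sub$is_pk])))
    }
  }
})

test_that("inverted-primary compounds sit in the right potency bands", {
  targets <- toy_targets()
  ia <- tibble::tibble(
    compound_key = c("a", "a", "b", "b", "c", "c"),
    target_id = c("PK01", "NP01", "PK01", "NP01", "PK01", "NP01"),
    uniprot = NA_character_,
    is_pk = rep(c(TRUE, FALSE), 3),
    ppot_final = c(5.3, 8.1,   7.2, 8.0,   5.5, 6.5),
    basis = "equilibrium", n_measurements = 1L
  )
  res <- count_inverted_primary(ia, targets)
  expect_equal(res$count, 1L)
  expect_equal(res$compounds, "a")  # b: PK too potent; c: non-PK too weak
})

test_that("profiles round-trip through the annotation-file schema", {
  rp <- random_profiles(7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_file(rp$profiles, path)
  back <- read_annotation_file(path)
  ord <- match(rp$profiles$compound_key, back$compound_key)
  expect_equal(back$pk_pd[ord], rp$profiles$pk_pd)
  expect_equal(back$nonpk_pd[ord], rp$profiles$nonpk_pd)
  expect_equal(back$pk_targets[ord], rp$profiles$pk_targets)
  expect_equal(back$nonpk_targets[ord], rp$profiles$nonpk_targets)
})
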