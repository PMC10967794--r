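test_that("class distributions count unique targets per level", {
  targets <- tibble::tibble(
    target_id = sprintf("T%02d", 1:10),
    uniprot = sprintf("U%02d", 1:10), name = sprintf("t%d", 1:10),
    is_pk = FALSE, kinase_group = NA_character_,
    class_l1 = c(rep("Enzyme", 4), rep("Membrane receptor", 3),
                 "Ion channel", "Transporter", "Unclassified"),
    class_l2 = c("Reductase", "Reductase", "Protease", "Hydrolase",
                 "7tm1", "7tm1", "7tm2", NA, NA, NA),
    is_antitarget = FALSE
  )
  d1 <- class_distribution(targets$target_id, targets, level = 1)
  expect_equal(d1$count[d1$class == "Enzyme"], 4L)
  expect_equal(d1$percentage[d1$class == "Enzyme"], 40.0)
  expect_equal(sum(d1$count), 10L)

  d2 <- class_distribution(targets$target_id, targets, level = 2,
                           within = "Enzyme")
  expect_equal(d2$count[d2$class == "Reductase"], 2L)
  expect_equal(d2$percentage[d2$class == "Reductase"], 50.0)
  d2m <- class_distribution(targets$target_id, targets, level = 2,
                            within = "Membrane receptor")
  expect_equal(d2m$percentage[d2m$class == "7tm1"], 66.7)

  one <- class_distribution(targets$target_id[1:4], targets, level = 1)
  expect_equal(one$percentage, 100.0)

  bad <- targets
  bad$class_l1[1] <- "Not a class"
  expect_error(class_distribution(bad$target_id, bad, level = 1),
               class = "pki_unknown_class")
  expect_error(class_distribution("T99", targets, level = 1),
               class = "pki_unknown_target")
})

test_that("planted class mix is recovered exactly from the catalog", {
  cat <- test_catalog()
  tt <- cat$target_table
  npk <- tt$target_id[!tt$is_pk & !tt$is_antitarget]
  d <- class_distribution(npk, tt, level = 1)
  expect_equal(sum(d$count), length(npk))
  for (cl in d$class) {
    expect_equal(d$count[d$class == cl], sum(tt$class_l1[match(npk, tt$target_id)] == cl))
  }
})

toy_net_profiles <- function() {
  tibble::tibble(
    compound_key = c("c1", "c2"),
    pk_targets = list(c("T1"), c("T1")),
    nonpk_targets = list(c("T2", "T3"), c("T2")),
    pk_pd = c(1L, 1L), nonpk_pd = c(2L, 1L)
  )
}

test_that("edges need the shared-inhibitor threshold; isolates are dropped", {
  net <- build_network(toy_net_profiles(), min_shared = 2)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$target_a, "T1")
  expect_equal(net$edges$target_b, "T2")
  expect_equal(net$edges$n_shared, 2L)
  expect_false("T3" %in% net$nodes$target_id)

  net1 <- build_network(toy_net_profiles(), min_shared = 1)
  expect_equal(nrow(net1$edges), 3L)  # T1-T2 (2), T1-T3 (1), T2-T3 (1)
  expect_true("T3" %in% net1$nodes$target_id)

  expect_error(build_network(toy_net_profiles(), min_shared = 0),
               class = "pki_bad_config")
})

test_that("network summaries count node domains and degrees", {
  net <- build_network(toy_net_profiles(), min_shared = 1)
  s <- network_summary(net)
  expect_equal(s$n_pk_nodes, 1L)
  expect_equal(s$n_nonpk_nodes, 2L)
  expect_equal(s$n_edges, 3L)
  expect_equal(s$top_nodes$target_id[1], "T1")
  expect_equal(sum(net$nodes$degree), 2L * nrow(net$edges))  # handshake
  # empty profile set gives an empty network
  empty <- build_network(toy_net_profiles()[0, ], min_shared = 2)
  se <- network_summary(empty)
  expect_equal(se$n_pk_nodes + se$n_nonpk_nodes + se$n_edges, 0L)
})

test_that("raising min_shared never adds nodes or edges", {
  rp <- random_profiles(5)
  n2 <- build_network(rp$profiles, min_shared = 2)
  n3 <- build_network(rp$profiles, min_shared = 3)
  expect_true(all(n3$nodes$target_id %in% n2$nodes$target_id))
  k2 <- paste(n2$edges$target_a, n2$edges$target_b)
  k3 <- paste(n3$edges$target_a, n3$edges$target_b)
  expect_true(all(k3 %in% k2))
  expect_lte(nrow(n3$edges), nrow(n2$edges))
})

test_that("network equals the pairwise-intersection brute force, 50 seeds", {
  for (seed in 1:50) {
    rp <- random_profiles(seed, n_compounds = 20, n_targets = 14)
    net <- build_network(rp$profiles, min_shared = 2)
    bf <- brute_force_edges(rp$profiles, min_shared = 2)
    expect_equal(net$edges$target_a, bf$target_a)
    expect_equal(net$edges$target_b, bf$target_b)
    expect_equal(net$edges$n_shared, bf$n_shared)
    # handshake on every instance
    expect_equal(sum(net$nodes$degree), 2L * nrow(net$edges))
  }
})

test_that("bipartite-only networks drop same-domain edges", {
  rp <- random_profiles(9)
  net <- build_network(rp$profiles, min_shared = 2, bipartite_only = TRUE)
  pk <- rp$target_ids[rp$is_pk]
  expect_true(all(xor(net$edges$target_a %in% pk,
                      net$edges$target_b %in% pk)))
})

test_that("GraphML export round-trips to an isomorphic attributed graph", {
  rp <- random_profiles(11)
  net <- build_network(rp$profiles, min_shared = 2)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, "graphml", path)
  back <- read_network_graphml(path)
  ord <- match(net$nodes$target_id, back$nodes$target_id)
  expect_equal(back$nodes$is_pk[ord], net$nodes$is_pk)
  expect_equal(back$nodes$degree[ord], net$nodes$degree)
  expect_equal(back$edges, net$edges)
})

test_that("SIF and edge-list exports use the documented line formats", {
  net <- build_network(toy_net_profiles(), min_shared = 2)
  sif <- withr::local_tempfile(fileext = ".sif")
  el <- withr::local_tempfile(fileext = ".txt")
  export_network(net, "sif", sif)
  export_network(net, "edgelist", el)
  expect_equal(readLines(sif), "T1 shares_PKIs T2")
  expect_equal(readLines(el), "T1 T2 2")
  # empty networks still produce valid (empty) documents
  empty <- build_network(toy_net_profiles()[0, ], min_shared = 2)
  g <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, "graphml", g)
  expect_equal(igraph::vcount(read_network_graphml(g)$graph), 0L)
})

test_that("a deposited-style annotation file reproduces network statistics", {
  cat <- test_catalog()
  recs <- catalog_records(cat)
  cur <- curate_interactions(recs, cat$target_table)
  qf <- apply_quality_filters(cur$interactions, cat$target_table)
  prof <- build_profiles(qf$interactions, cat$target_table)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_file(prof, path)
  prof2 <- read_annotation_file(path)
  direct <- network_summary(build_network(prof, min_shared = 2))
  fromfile <- network_summary(build_network(prof2, min_shared = 2))
  expect_equal(fromfile$n_pk_nodes, direct$n_pk_nodes)
  expect_equal(fromfile$n_nonpk_nodes, direct$n_nonpk_nodes)
  expect_equal(fromfile$n_edges, direct$n_edges)
})
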