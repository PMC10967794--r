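#' @title End-to-end pipeline
#' @description One-call composition of the whole workflow: ingest raw
#'   activity tables, curate, quality-filter, profile promiscuity, rank,
#'   scan potency levels, classify targets, build and export the
#'   shared-inhibitor network and the kinome annotation, with every
#'   artifact written as a deterministic TSV and a plain-text run log
#'   recording configuration, toolkit versions and per-stage counts.
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' Defaults reproduce the reference analysis settings: activity threshold
#' pPot 5 (10 uM), replicate-consistency cutoff 1 log unit (span rule for
#' kinase pairs, SD rule for non-kinase pairs), network edge threshold 2
#' shared inhibitors, potency-scan thresholds 5/6/7/8, degree bins
#' 1 / 2-4 / 5-9 / 10+.
#'
#' @param chembl_path,bindingdb_path paths to the raw activity tables
#'   (either may be `NULL`).
#' @param target_path path to the target-metadata table.
#' @param output_dir run directory for all artifacts.
#' @param chembl_column_map,bindingdb_column_map optional column maps, see
#'   [read_activity_table()].
#' @param ppot_min activity threshold on the pPot scale.
#' @param consistency_cutoff replicate-consistency cutoff in log units.
#' @param consistency_rule `"auto"`, `"span"` or `"sd"`.
#' @param vocabulary contradiction vocabulary.
#' @param interference_catalog_path,chemistry_catalog_path substructure
#'   catalogs (`NULL` = shipped defaults).
#' @param salt_list_path salt/solvent list (`NULL` = shipped default).
#' @param antitarget_min_ppot potency an anti-target interaction must reach
#'   to disqualify a compound (`NULL` = any reported activity).
#' @param min_shared network edge threshold.
#' @param scan_thresholds potency-scan thresholds.
#' @param bins degree bins, see [default_pd_bins()].
#' @param nonpk_nanomolar_min,pk_micromolar_band bands for
#'   [count_inverted_primary()].
#' @param name_map_path kinase name map (`NULL` = target names).
#' @param seed seed recorded in the run log.
#' @return list of class `pki_config`.
#' @export
pki_config <- function(chembl_path = NULL, bindingdb_path = NULL,
                       target_path = NULL, output_dir = tempfile("pki_run_"),
                       chembl_column_map = NULL, bindingdb_column_map = NULL,
                       ppot_min = 5.0, consistency_cutoff = 1.0,
                       consistency_rule = "auto",
                       vocabulary = default_contradiction_vocabulary(),
                       interference_catalog_path = NULL,
                       chemistry_catalog_path = NULL, salt_list_path = NULL,
                       antitarget_min_ppot = NULL, min_shared = 2,
                       scan_thresholds = c(5, 6, 7, 8),
                       bins = default_pd_bins(), nonpk_nanomolar_min = 7.0,
                       pk_micromolar_band = c(5.0, 6.0),
                       name_map_path = NULL, seed = 1L) {
  structure(as.list(environment()), class = "pki_config")
}

#' Run the full pipeline
#'
#' Executes every stage and writes all artifacts into
#' `config$output_dir`: curated interactions, discard ledgers, standardized
#' compounds, quality-filter verdicts, promiscuity profiles (also in the
#' annotation-file schema), degree distributions, target and compound
#' rankings, the potency scan, target-class distributions, the
#' shared-inhibitor network (GraphML/SIF/edge list + JSON summary), the
#' kinome annotation CSV and a run log. A fatal error in any stage aborts
#' with the stage name.
#'
#' @param config `pki_config` object.
#' @return (invisibly) list with the in-memory artifacts (`interactions`,
#'   `profiles`, `network`, `summary`, ...) and `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pki_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      pki_abort(paste0("stage ", name, ": ", conditionMessage(e)),
                "pki_stage_error")
    })
  }
  log_lines <- c(
    "pkitargets run log",
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("pkitargets version: ",
           as.character(utils::packageVersion("pkitargets"))),
    paste0("structure toolkit: ChemmineOB ",
           as.character(utils::packageVersion("ChemmineOB")),
           " (OpenBabel backend; compound keys are toolkit-dependent)"),
    paste0("seed: ", config$seed),
    "tautomers are not merged",
    ""
  )

  # io_ingest
  ingests <- stage("io_ingest", {
    if (is.null(config$target_path) || !file.exists(config$target_path)) {
      pki_abort("target table missing", "pki_io_error")
    }
    targets <- read_target_table(config$target_path)
    recs <- list()
    rejects <- list()
    if (!is.null(config$chembl_path)) {
      r <- read_activity_table(config$chembl_path, "chembl",
                               config$chembl_column_map)
      recs$chembl <- r$records
      rejects$chembl <- r$rejected
    }
    if (!is.null(config$bindingdb_path)) {
      r <- read_activity_table(config$bindingdb_path, "bindingdb",
                               config$bindingdb_column_map)
      recs$bindingdb <- r$records
      rejects$bindingdb <- r$rejected
    }
    if (length(recs) == 0L) {
      pki_abort("no activity table given", "pki_io_error")
    }
    list(records = dplyr::bind_rows(recs), targets = targets,
         parse_rejected = dplyr::bind_rows(rejects, .id = "dialect"))
  })
  n_in <- nrow(ingests$records) + nrow(ingests$parse_rejected)
  log_lines <- c(log_lines,
                 paste0("rows read: ", n_in),
                 paste0("records parsed: ", nrow(ingests$records)),
                 paste0("rows rejected at parse: ", nrow(ingests$parse_rejected)))

  salt_list <- if (is.null(config$salt_list_path)) {
    default_salt_list()
  } else {
    default_salt_list(config$salt_list_path)
  }

  # curate (includes standardize)
  cur <- stage("curate", curate_interactions(
    ingests$records, ingests$targets, ppot_min = config$ppot_min,
    consistency_cutoff = config$consistency_cutoff,
    consistency_rule = config$consistency_rule,
    vocabulary = config$vocabulary, salt_list = salt_list
  ))
  log_lines <- c(log_lines,
                 paste0("records failing confidence rules: ",
                        nrow(cur$discards$records)),
                 paste0("structures rejected: ", nrow(cur$discards$structures)),
                 paste0("contradicted pairs dropped: ",
                        nrow(cur$discards$contradicted_pairs)),
                 paste0("inconsistent groups discarded: ",
                        nrow(cur$discards$inconsistent_groups)),
                 paste0("curated interactions (pPot >= ", config$ppot_min,
                        "): ", nrow(cur$interactions)))

  # quality_filters
  qf <- stage("quality_filters", {
    icat <- if (is.null(config$interference_catalog_path)) {
      NULL
    } else {
      load_pattern_catalog(config$interference_catalog_path)
    }
    ccat <- if (is.null(config$chemistry_catalog_path)) {
      NULL
    } else {
      load_pattern_catalog(config$chemistry_catalog_path)
    }
    apply_quality_filters(cur$interactions, ingests$targets,
                          interference_catalog = icat,
                          chemistry_catalog = ccat,
                          antitarget_min_ppot = config$antitarget_min_ppot)
  })
  log_lines <- c(log_lines,
                 paste0("compounds removed (interference): ",
                        length(qf$removed_interference)),
                 paste0("compounds removed (chemistry rules): ",
                        length(setdiff(qf$removed_chemistry,
                                       qf$removed_interference))),
                 paste0("compounds removed (anti-targets): ",
                        nrow(qf$removed_antitarget)))

  # promiscuity
  prom <- stage("promiscuity", {
    profiles <- build_profiles(qf$interactions, ingests$targets)
    final <- qf$interactions[qf$interactions$compound_key %in%
                               profiles$compound_key, ]
    list(
      profiles = profiles,
      interactions = final,
      pk_dist = bin_distribution(profiles, "pk", config$bins),
      nonpk_dist = bin_distribution(profiles, "nonpk", config$bins),
      top_pk = rank_targets_by_shared_inhibitors(profiles, "pk", 10,
                                                 ingests$targets),
      top_nonpk = rank_targets_by_shared_inhibitors(profiles, "nonpk", 10,
                                                    ingests$targets),
      top_compounds = rank_compounds_by_nonpk_targets(profiles, 10),
      scan = potency_scan(final, ingests$targets, config$scan_thresholds),
      inverted = count_inverted_primary(final, ingests$targets,
                                        config$nonpk_nanomolar_min,
                                        config$pk_micromolar_band)
    )
  })
  log_lines <- c(log_lines,
                 paste0("analysis-set compounds: ", nrow(prom$profiles)),
                 paste0("unique kinase targets: ",
                        length(unique(unlist(prom$profiles$pk_targets)))),
                 paste0("unique non-kinase targets: ",
                        length(unique(unlist(prom$profiles$nonpk_targets)))),
                 paste0("inverted-primary compounds: ", prom$inverted$count))

  # classify_network
  net <- stage("classify_network", {
    nonpk_ids <- unique(unlist(prom$profiles$nonpk_targets))
    cls1 <- class_distribution(nonpk_ids, ingests$targets, level = 1)
    cls2e <- tryCatch(class_distribution(nonpk_ids, ingests$targets, 2,
                                         within = "Enzyme"),
                      error = function(e) tibble::tibble())
    cls2m <- tryCatch(class_distribution(nonpk_ids, ingests$targets, 2,
                                         within = "Membrane receptor"),
                      error = function(e) tibble::tibble())
    network <- build_network(prom$profiles, min_shared = config$min_shared)
    list(cls1 = cls1, cls2_enzyme = cls2e, cls2_membrane = cls2m,
         network = network, summary = network_summary(network))
  })
  log_lines <- c(log_lines,
                 paste0("network: ", net$summary$n_pk_nodes, " PK nodes, ",
                        net$summary$n_nonpk_nodes, " non-PK nodes, ",
                        net$summary$n_edges, " edges"))

  # kinmap_export
  km <- stage("kinmap_export", {
    nm <- if (is.null(config$name_map_path)) {
      NULL
    } else {
      read_name_map(config$name_map_path)
    }
    annotate_kinome(prom$profiles, ingests$targets, name_map = nm)
  })

  # write artifacts
  od <- config$output_dir
  stage("report", {
    write_table(cur$interactions, file.path(od, "curated_interactions.tsv"))
    write_table(prom$interactions, file.path(od, "final_interactions.tsv"))
    write_table(ingests$parse_rejected, file.path(od, "rejected_rows.tsv"))
    write_table(cur$discards$records, file.path(od, "discard_records.tsv"))
    write_table(cur$discards$contradicted_pairs,
                file.path(od, "discard_contradicted_pairs.tsv"))
    write_table(cur$discards$inconsistent_groups,
                file.path(od, "discard_inconsistent_groups.tsv"))
    write_table(cur$compounds, file.path(od, "compounds.tsv"))
    write_table(qf$verdicts, file.path(od, "quality_verdicts.tsv"))
    write_table(qf$removed_antitarget,
                file.path(od, "removed_antitarget_compounds.tsv"))
    prof_flat <- prom$profiles
    write_table(prof_flat, file.path(od, "profiles.tsv"))
    write_annotation_file(prom$profiles, file.path(od, "annotation_file.tsv"))
    write_table(prom$pk_dist, file.path(od, "pk_pd_distribution.tsv"))
    write_table(prom$nonpk_dist, file.path(od, "nonpk_pd_distribution.tsv"))
    write_table(prom$top_pk, file.path(od, "top_pk_targets.tsv"))
    write_table(prom$top_nonpk, file.path(od, "top_nonpk_targets.tsv"))
    write_table(prom$top_compounds, file.path(od, "top_compounds.tsv"))
    write_table(prom$scan, file.path(od, "potency_scan.tsv"))
    write_table(net$cls1, file.path(od, "class_distribution_l1.tsv"))
    if (nrow(net$cls2_enzyme) > 0L) {
      write_table(net$cls2_enzyme, file.path(od, "class_l2_enzyme.tsv"))
    }
    if (nrow(net$cls2_membrane) > 0L) {
      write_table(net$cls2_membrane,
                  file.path(od, "class_l2_membrane_receptor.tsv"))
    }
    export_network(net$network, "graphml", file.path(od, "network.graphml"))
    export_network(net$network, "sif", file.path(od, "network.sif"))
    export_network(net$network, "edgelist",
                   file.path(od, "network_edgelist.txt"))
    jsonlite::write_json(
      list(n_pk_nodes = net$summary$n_pk_nodes,
           n_nonpk_nodes = net$summary$n_nonpk_nodes,
           n_edges = net$summary$n_edges),
      file.path(od, "network_summary.json"), auto_unbox = TRUE)
    write_kinmap_annotation(km$annotations,
                            file.path(od, "kinmap_annotation.csv"))
    write_table(km$unmapped, file.path(od, "kinmap_unmapped.tsv"))
    writeLines(log_lines, file.path(od, "run_log.txt"))
  })

  invisible(list(output_dir = od, targets = ingests$targets,
                 interactions = prom$interactions, curated = cur,
                 quality = qf, profiles = prom$profiles,
                 distributions = list(pk = prom$pk_dist,
                                      nonpk = prom$nonpk_dist),
                 scan = prom$scan, inverted = prom$inverted,
                 classes = net[c("cls1", "cls2_enzyme", "cls2_membrane")],
                 network = net$network, summary = net$summary,
                 kinmap = km))
}
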