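#' @title Target classification and the shared-inhibitor network
#' @description Non-kinase targets are binned by their level-1 protein
#'   class (enzymes and membrane receptors further by level 2), and all
#'   targets of the analysis set are joined into a network in which two
#'   targets are connected iff they share at least `min_shared` inhibitors.
#'   Targets without any qualifying edge are excluded from the node set by
#'   default, matching a drawn network that only shows connected targets.
#' @name classify_network
NULL

#' Target-class distribution of the analysis set
#'
#' Counts unique non-kinase targets per protein class. At level 1 all
#' targets are binned by `class_l1`; at level 2 the targets of one level-1
#' class (`within`, e.g. `"Enzyme"` or `"Membrane receptor"`) are binned by
#' `class_l2`. An unclassified or unknown class string is fatal.
#'
#' @param target_ids character vector of (non-kinase) target IDs in the
#'   analysis set.
#' @param targets target-metadata tibble.
#' @param level 1 or 2.
#' @param within level-1 class to drill into when `level = 2`.
#' @return tibble with `class`, `count`, `percentage` (half-up, 1 decimal;
#'   percentages are of the binned target set).
#' @export
class_distribution <- function(target_ids, targets, level = 1,
                               within = "Enzyme") {
  ids <- unique(target_ids)
  idx <- match(ids, targets$target_id)
  if (anyNA(idx)) {
    pki_abort(paste0("targets absent from metadata: ",
                     paste(ids[is.na(idx)], collapse = ", ")),
              "pki_unknown_target")
  }
  meta <- targets[idx, ]
  if (level == 1) {
    cls <- meta$class_l1
  } else {
    meta <- meta[meta$class_l1 == within, ]
    cls <- meta$class_l2
  }
  if (anyNA(cls) || any(!nzchar(cls))) {
    pki_abort("unknown (missing) class annotation", "pki_unknown_class")
  }
  if (level == 1 && !all(cls %in% chembl_class_levels())) {
    pki_abort(paste0("unknown class string: ",
                     paste(setdiff(cls, chembl_class_levels()), collapse = ", ")),
              "pki_unknown_class")
  }
  tab <- sort(table(cls), decreasing = TRUE)
  tibble::tibble(
    class = names(tab),
    count = as.integer(tab),
    percentage = round_half_up(100 * as.integer(tab) / sum(tab), 1)
  )
}

#' Build the shared-inhibitor target network
#'
#' Nodes are targets of the analysis-set profiles; an undirected edge
#' `(t1, t2)` with weight `n_shared` exists iff at least `min_shared`
#' compounds are active against both targets. Isolated targets (no
#' qualifying edge) are excluded unless `include_isolates = TRUE`;
#' `bipartite_only = TRUE` restricts edges to kinase / non-kinase pairs.
#'
#' @param profiles profile tibble from [build_profiles()].
#' @param min_shared minimal shared-compound count per edge (default 2).
#' @param include_isolates keep targets without edges as isolated nodes.
#' @param bipartite_only drop kinase-kinase and non-kinase-non-kinase
#'   edges.
#' @return object of class `pki_target_network`: list with `nodes` (tibble:
#'   `target_id`, `is_pk`, `degree`), `edges` (tibble: `target_a`,
#'   `target_b`, `n_shared`) and `graph` (igraph object with the same
#'   attributes).
#' @export
build_network <- function(profiles, min_shared = 2, include_isolates = FALSE,
                          bipartite_only = FALSE) {
  if (min_shared < 1) {
    pki_abort("min_shared must be >= 1", "pki_bad_config")
  }
  all_targets <- lapply(seq_len(nrow(profiles)), function(i) {
    c(profiles$pk_targets[[i]], profiles$nonpk_targets[[i]])
  })
  pk_ids <- unique(unlist(profiles$pk_targets))
  target_pool <- sort(unique(unlist(all_targets)))

  pair_keys <- unlist(lapply(all_targets, function(ts) {
    ts <- sort(unique(ts))
    if (length(ts) < 2L) {
      return(character(0))
    }
    cmb <- utils::combn(ts, 2L)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  }))
  if (is.null(pair_keys)) {
    pair_keys <- character(0)
  }
  tab <- table(pair_keys)
  keys <- names(tab)
  if (is.null(keys)) {
    keys <- character(0)
  }
  counts <- as.integer(tab)
  keep <- counts >= min_shared
  parts <- strsplit(keys[keep], "\r", fixed = TRUE)
  edges <- tibble::tibble(
    target_a = vapply(parts, `[`, "", 1L),
    target_b = vapply(parts, `[`, "", 2L),
    n_shared = counts[keep]
  )
  if (bipartite_only && nrow(edges) > 0L) {
    cross <- xor(edges$target_a %in% pk_ids, edges$target_b %in% pk_ids)
    edges <- edges[cross, ]
  }
  edges <- edges[order(edges$target_a, edges$target_b, method = "radix"), ]

  node_ids <- if (include_isolates) {
    target_pool
  } else {
    sort(unique(c(edges$target_a, edges$target_b)))
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = node_ids, stringsAsFactors = FALSE)
  )
  igraph::V(g)$is_pk <- node_ids %in% pk_ids
  igraph::V(g)$degree <- igraph::degree(g)
  igraph::E(g)$n_shared <- edges$n_shared
  nodes <- tibble::tibble(
    target_id = node_ids,
    is_pk = node_ids %in% pk_ids,
    degree = as.integer(igraph::degree(g))
  )
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "pki_target_network")
}

#' Summarize a target network
#'
#' @param net `pki_target_network` from [build_network()].
#' @param k rows of the top-degree node table.
#' @return list with `n_pk_nodes`, `n_nonpk_nodes`, `n_edges` and
#'   `top_nodes` (tibble sorted by degree descending, ties by target ID).
#' @export
network_summary <- function(net, k = 10) {
  nodes <- net$nodes
  top <- nodes[order(-nodes$degree, nodes$target_id, method = "radix"), ]
  list(
    n_pk_nodes = sum(nodes$is_pk),
    n_nonpk_nodes = sum(!nodes$is_pk),
    n_edges = nrow(net$edges),
    top_nodes = utils::head(top, k)
  )
}

#' Export a target network
#'
#' GraphML output carries node attributes `is_pk` and `degree` and the
#' edge attribute `n_shared`; SIF uses the interaction label
#' `shares_PKIs`; the edge list is whitespace-separated
#' `target_a target_b n_shared`. Element order is deterministic.
#'
#' @param net `pki_target_network`.
#' @param format `"graphml"`, `"sif"` or `"edgelist"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, format = c("graphml", "sif", "edgelist"),
                           path) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else if (format == "sif") {
    lines <- if (nrow(net$edges) > 0L) {
      paste(net$edges$target_a, "shares_PKIs", net$edges$target_b)
    } else {
      character(0)
    }
    writeLines(lines, path)
  } else {
    lines <- if (nrow(net$edges) > 0L) {
      paste(net$edges$target_a, net$edges$target_b, net$edges$n_shared)
    } else {
      character(0)
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a GraphML network export back
#'
#' @param path GraphML file written by [export_network()].
#' @return `pki_target_network` with `nodes`, `edges`, `graph`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble::tibble(
    target_id = igraph::V(g)$name,
    is_pk = as.logical(igraph::V(g)$is_pk),
    degree = as.integer(igraph::V(g)$degree)
  )
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(
    target_a = pmin(el[, 1], el[, 2]),
    target_b = pmax(el[, 1], el[, 2]),
    n_shared = as.integer(igraph::E(g)$n_shared)
  )
  edges <- edges[order(edges$target_a, edges$target_b, method = "radix"), ]
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "pki_target_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
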