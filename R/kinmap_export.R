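#' @title Kinome-tree annotation export
#' @description Kinases sharing inhibitors with non-kinase targets can be
#'   mapped onto a phylogenetic tree of the human kinome by an external
#'   viewer (KinMap-style). This module computes, per kinase of the
#'   analysis set, the number of distinct non-kinase targets of its shared
#'   inhibitors and writes it as the node size/color attribute of a
#'   two-attribute annotation CSV. The writer is template-driven so the
#'   exact column naming can follow the viewer's schema.
#' @name kinmap_export
NULL

#' Annotate the kinome with non-kinase counterpart counts
#'
#' For every kinase hit by at least one analysis-set compound, the
#' annotation value is the size of the union of non-kinase targets over the
#' compounds hitting that kinase — identical to the counterpart count of
#' [rank_targets_by_shared_inhibitors()] with `domain = "pk"`. Kinases
#' missing from the name map are reported, not fatal.
#'
#' @param profiles profile tibble from [build_profiles()].
#' @param targets target-metadata tibble (for UniProt accessions and kinase
#'   groups).
#' @param name_map tibble with columns `uniprot` and `kinase_name` mapping
#'   accessions to the external tree's kinase names; `NULL` falls back to
#'   the target's own name.
#' @return list with `annotations` (tibble: `kinase_name`, `group`,
#'   `size_value`, `color_value`, `target_id`, `uniprot`) and `unmapped`
#'   (tibble of kinases without a tree name).
#' @export
annotate_kinome <- function(profiles, targets, name_map = NULL) {
  ranked <- rank_targets_by_shared_inhibitors(profiles, domain = "pk",
                                              k = Inf)
  idx <- match(ranked$target_id, targets$target_id)
  ann <- tibble::tibble(
    target_id = ranked$target_id,
    uniprot = targets$uniprot[idx],
    group = targets$kinase_group[idx],
    size_value = as.integer(ranked$n_counterpart_targets),
    color_value = as.integer(ranked$n_counterpart_targets)
  )
  if (!is.null(name_map)) {
    ann$kinase_name <- name_map$kinase_name[match(ann$uniprot, name_map$uniprot)]
  } else {
    ann$kinase_name <- targets$name[idx]
  }
  unmapped <- ann[is.na(ann$kinase_name), c("target_id", "uniprot")]
  ann <- ann[!is.na(ann$kinase_name),
             c("kinase_name", "group", "size_value", "color_value",
               "target_id", "uniprot")]
  ann <- ann[order(ann$kinase_name, method = "radix"), ]
  list(annotations = ann, unmapped = unmapped)
}

#' Write a kinome-tree annotation CSV
#'
#' @param annotations annotation tibble from [annotate_kinome()].
#' @param path output CSV path.
#' @param template named character vector giving the output column names
#'   for the kinase name, size and color attributes (KinMap-style default:
#'   `xName`, `size`, `color`).
#' @return `path`, invisibly.
#' @export
write_kinmap_annotation <- function(annotations, path,
                                    template = c(name = "xName",
                                                 size = "size",
                                                 color = "color")) {
  out <- tibble::tibble(
    annotations$kinase_name,
    annotations$size_value,
    annotations$color_value
  )
  names(out) <- unname(template[c("name", "size", "color")])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a kinase name map
#'
#' Two-column TSV mapping UniProt accessions to external kinome-tree
#' kinase names; the shipped `kinmap_name_map.tsv` is an editable fixture
#' seeded with a handful of well-known kinases.
#'
#' @param path TSV with columns `uniprot`, `kinase_name`.
#' @return tibble with `uniprot`, `kinase_name`.
#' @export
read_name_map <- function(path = system.file("extdata", "kinmap_name_map.tsv",
                                             package = "pkitargets")) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  tibble::tibble(uniprot = raw$uniprot, kinase_name = raw$kinase_name)
}
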