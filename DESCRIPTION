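Package: pkitargets
Title: Non-Kinase Target Profiling of Protein Kinase Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A curation and analysis pipeline for identifying and profiling
    non-kinase targets of human protein kinase inhibitors from public
    bioactivity data. Parses ChEMBL-style and BindingDB-style activity
    exports, standardizes compound structures (salt stripping,
    neutralization, removal of stereochemistry) to non-stereo canonical
    SMILES aggregation keys, applies high-confidence curation rules
    (single-protein human targets, direct binding assays, exact potency
    relations, replicate consistency on the log-potency scale), screens
    assay-interference and anti-target liabilities, computes per-compound
    kinase and non-kinase promiscuity degrees, builds the shared-inhibitor
    target network, and exports kinome-tree annotations. Includes a
    synthetic-data generator with a planted ground-truth manifest so every
    pipeline stage is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
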