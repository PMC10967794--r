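---
title: "Methods: curating and profiling non-kinase targets of kinase inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating and profiling non-kinase targets of kinase inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Most small-molecule protein kinase (PK) inhibitors (PKIs) bind at or near
the ATP cofactor site, which is conserved across the human kinome, so
multi-kinase activity is common. Beyond the kinome, PKIs can also engage
functionally unrelated proteins — GPCRs, epigenetic regulators, metabolic
enzymes — and such secondary targets matter both for polypharmacology and
for adverse-effect risk. Finding them reliably in public bioactivity data
is primarily a *curation* problem: public databases mix direct binding
measurements with single-point screens, replicate values disagree, the
same parent compound appears as salts and stereoisomers under different
IDs, and assay-interference chemotypes generate false positives.
`pkitargets` implements that curation and the downstream promiscuity
analysis as a tested pipeline, with a synthetic-data generator that plants
known ground truth so every stage can be verified end to end.

## The record model and confidence rules

Activity rows from two export dialects (ChEMBL-style and BindingDB-style)
are parsed into one record model. Fields one dialect lacks (assay
relationship, confidence score in BindingDB-style exports) stay absent
rather than being defaulted, because the confidence rules are
dialect-specific:

* ChEMBL-style records pass only as direct binding assays (relationship
  type `D`) at confidence score 9 against `SINGLE PROTEIN` targets of
  *Homo sapiens*, with relation `"="` and unit nM.
* BindingDB-style records pass as human single-protein chains with
  relation `"="`.
* Both dialects are restricted to IC50, Ki and Kd endpoints. Single-point
  readouts ("% inhibition" and the like) are rejected at parse time;
  accepting them would trade a lower false-negative rate for exactly the
  false positives a promiscuity analysis must avoid.

Every rejected row carries the name of the first rule it failed; nothing
is dropped silently, and row counts are conserved (`rows in = records out
+ rejections out`), which the test suite asserts as an invariant.

## Structure standardization and the aggregation key

Measurements are pooled per *compound*, not per database entry. The
pooling key is the non-stereo canonical SMILES of the neutralized parent
component:

1. neutralize protonation states (OpenBabel's `neutralize` operation;
   permanently charged centers such as quaternary nitrogen stay charged),
2. split into covalently connected components,
3. drop components without carbon, then drop components on a configurable
   salt/solvent list — but never the last fragment standing, so a lone
   acetic acid (or an ethanol·HCl pair) still yields a parent,
4. keep the largest remaining component by heavy-atom count, breaking
   ties by the lexicographically smallest canonical form,
5. return its canonical SMILES with stereochemistry and isotope labels
   erased.

The step is idempotent (a returned key re-standardizes to itself), and
tautomers are deliberately *not* merged — tautomer canonicalization is a
much harder, toolkit-dependent normalization, and the run log records
that choice. Canonicalization is delegated to OpenBabel via ChemmineOB;
because canonical forms are toolkit-dependent, the run log records the
toolkit name and version with every run.

## Replicate pooling and the final annotation

Potencies are converted to the negative decadic log scale
(`pPot = 9 − log10(value in nM)`; 10 µM ↔ pPot 5). Replicates of one
endpoint for one compound–target pair are pooled across both source
dialects (targets are resolved by UniProt accession) and averaged only if
mutually consistent:

* kinase pairs use the **span rule**: all values in the same order of
  magnitude, operationalized as `max − min < 1` log unit. A span of
  exactly one log unit is *not* "the same order of magnitude" and is
  discarded.
* non-kinase pairs use the **SD rule**: population standard deviation
  ≤ 1 log unit; strictly larger is discarded. The population (not
  sample) estimator is used, so two values 2 log units apart (SD exactly
  1.0) sit on the retained boundary.

Both boundaries are configurable. Ki and Kd are distinct endpoints and
are averaged separately; equilibrium constants take priority over the
assay-dependent IC50, and the **highest** surviving Ki/Kd average is the
final annotation (falling back to the IC50 average). We max over *group
averages*, not raw values — the alternative reading (max over raw
values) would make the consistency screen irrelevant for the final
value. Pairs carrying a contradictory comment ("inactive",
"inconclusive", "not active"; case-insensitive, configurable) lose all
their records before pooling. Finally, a minimal potency of pPot ≥ 5
(10 µM, boundary inclusive) is required.

## Compound-level quality filters

Three compound-level predicates follow; because each acts on whole
compounds, their application order cannot change the final set:

* **interference screening** against a shipped PAINS-style pattern
  subset (quinones, catechols, rhodanines, azo/hydrazone motifs, ...),
* **chemistry rules**: a shipped subset of reactive / assay-hostile
  structural alerts (acyl halides, epoxides, Michael acceptors,
  peroxides, ...). This is a documented stand-in engine: full
  medicinal-chemistry rule programs add demerit scoring and property
  cutoffs, which are out of scope here; both catalogs are plain TSV
  files the user can replace,
* **anti-target removal**: any compound with a retained interaction
  against a target flagged as anti-target (hERG, CYP isoforms, serum
  albumin, ...) is removed entirely. By default *any* reported activity
  triggers removal; a configuration flag can require a potency level.
  The anti-target list itself lives in the target table and is therefore
  fully configurable.

## Promiscuity degrees, rankings, potency scan

A compound's PK promiscuity degree (`PK_PD`) is its number of distinct
kinase targets; `Non-PK_PD` counts non-kinase targets. The analysis set
is exactly the compounds with at least one of each. Degree distributions
are binned as 1 / 2–4 / 5–9 / 10+; the 5–9 bin completes the partition
between the named "two to four" and "10 or more" bins and is
configurable. Percentages are rounded half-up to one decimal to match
printed-report style (base R's round-half-to-even would print 17.05% as
17.0 rather than 17.1).

Targets are ranked by the number of analysis-set compounds hitting them,
together with the size of the union of counterpart-domain targets of
those compounds; compounds are ranked by `Non-PK_PD` (ties:
`PK_PD`, then key). The potency scan re-counts unique kinase and
non-kinase targets at thresholds 5/6/7/8, holding the compound set fixed
at the base threshold, so both columns are non-increasing by
construction. The "inverted-primary" query counts compounds with
nanomolar non-kinase activity but only micromolar kinase activity; since
no numeric bands are fixed by convention, we operationalize nanomolar as
pPot ≥ 7 and the micromolar band as 5 ≤ pPot < 6, both exposed as
configuration.

## Target classes and the shared-inhibitor network

Non-kinase targets are binned by level-1 protein class (ten classes:
enzyme, membrane receptor, epigenetic regulator, ion channel,
transcription factor, transporter, secreted protein, cytosolic other
protein, other, unclassified), with level-2 drill-down for enzymes and
membrane receptors.

The target network connects two targets iff they share at least two
analysis-set inhibitors. Targets without any qualifying edge are
excluded from the node set by default — a drawn network shows only
connected targets, and including isolates is a flag. Edges between
same-domain pairs (kinase–kinase, non-kinase–non-kinase) are included by
default; a bipartite-only switch restricts to cross-domain edges.
Exports are GraphML (node attributes `is_pk`, `degree`; edge attribute
`n_shared`), SIF with interaction label `shares_PKIs`, and a plain edge
list; element order is deterministic so repeated runs are
byte-identical. The kinome annotation export writes, per kinase, the
number of distinct non-kinase targets of its shared inhibitors as a
two-attribute (size/color) CSV in the style of external kinome-tree
viewers; the column naming is template-driven so schema drift is a
configuration edit, and kinases missing from the UniProt→tree-name map
go to a sidecar file instead of failing the export.

## The synthetic-data generator

The generator emulates exactly the pathologies the pipeline exists to
handle, with a ground-truth manifest that *fully determines* the
expected output of every stage under the default configuration:

* structures are combinatorial amide/ester scaffolds (chain × linker ×
  ring, extended with branch prefixes when more unique parents are
  needed); interference decoys embed a para-quinone motif matched by the
  shipped catalog;
* a configurable fraction of compounds is also emitted as salt (`.Cl`)
  and stereo (`[C@@H]`) variants under distinct source IDs;
* true pPot values are drawn uniformly on [5.2, 9.5] with a
  sub-micromolar stratum (default 60% above pPot 6.2) so potency scans
  have signal;
* replicate noise is Gaussian on the pPot scale (log-normal assay
  error). For planted-consistent groups the group-level offset is
  truncated to ±0.15 and within-group deviations to ±0.45 and centered,
  which guarantees span < 0.9, population SD ≤ 0.45 and group mean
  ≥ 5.05 — so consistency rules and the activity threshold provably
  retain them. Planted-inconsistent groups use ±1.3 offsets (span 2.6,
  SD 1.3), violating both rules;
* planted contradictions add an "inactive"-commented row that passes
  every record-level filter, so the pair-level drop rule is what removes
  it; planted relation (`>`) and wrong-organism rows exercise the
  confidence filter without affecting expected results;
* anti-target hits are kept clean (never contradicted or inconsistent)
  so flagged compounds are always removable;
* each measurement row is assigned to the ChEMBL-style or BindingDB-style
  table at random (default 30% BindingDB), so cross-database pooling by
  UniProt is exercised everywhere.

What the generator does **not** emulate: real chemical diversity, real
kinome coverage and target identities, correlated assay biases,
activity-cliff structure, or database-scale volumes. Passing the
recovery tests therefore demonstrates that the pipeline's *logic* is
exact under its stated rules, not that real-database curation is free of
judgment calls (e.g., which comments count as contradictions).

Stress scenarios regenerate tables from a manifest: `all_consistent`
(empty discard ledger), `heavy_noise` (untruncated SD 1.5 noise, checked
against a brute-force span/SD recount) and `threshold_edge` (true
values cycling 4.99/5.00/5.01 emitted noise-free, so threshold
inclusivity is observable).

## Numerical and design choices

* Population SD, strict `> 1` discard; span strict `< 1` retention (both
  documented above and config-overridable).
* Equilibrium tie-break: among surviving Ki/Kd group averages the
  maximum wins; an exact tie between Ki and Kd resolves by endpoint name
  for determinism.
* Ranking and node orderings break ties by target ID / compound key;
  all written tables are sorted, so identical inputs give byte-identical
  outputs.
* `9 − log10(nM)` is exact for the 10 µM ↔ pPot 5 anchor; values are
  emitted at 10 significant digits, so write/read round trips are
  lossless at the comparison tolerances used in the tests.
* Problem sizes in the test suite: the shared catalog uses 40 compounds;
  curation-oracle equivalence runs on a 100-compound catalog (~1,200
  records); end-to-end recovery on 200 compounds with noise SD 0.2;
  property suites use 50 seeded random instances each; the
  degree-distribution shape check draws 2,000 compounds (manifest only).
  These sizes give exact set-level assertions in seconds while covering
  every planted pathology.

## Known limitations

* Compound keys are OpenBabel-canonical; a different toolkit yields
  different (equally valid) keys, which is why the run log records the
  toolkit version. Keys are not InChI-based by design.
* No tautomer merging, no assay-condition modeling (e.g. ATP
  concentration for IC50s), no mutant-protein handling.
* The chemistry-rule engine is substructure-only — no demerit scores or
  physicochemical-property cutoffs.
* The network module computes no layout; rendering is left to external
  viewers.

## Reproducing an analysis

```r
library(pkitargets)

cat <- generate_catalog(n_compounds = 200, seed = 1)
paths <- write_catalog(cat, "raw")
conf <- pki_config(chembl_path = paths[["chembl"]],
                   bindingdb_path = paths[["bindingdb"]],
                   target_path = paths[["targets"]],
                   output_dir = "run")
res <- run_pipeline(conf)
res$summary
```

`scripts/acceptance.R` (repository root) recomputes the package's
headline quantities from scratch and writes them as JSON; see the README
for how to run it.
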