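---
title: "glandmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glandmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glandmap)
```

## What this package computes

Sjögren's Disease (SjD) is an autoimmune exocrinopathy in which lymphocytes
infiltrate the salivary and lacrimal glands and secretory epithelium is
lost. Dissecting which epithelial populations are targeted, which immune
populations expand, and which cell types physically co-occur requires a
stack of small, well-defined computations over three kinds of data:

* sparse cell × gene count matrices from single-cell RNA-seq, with
  per-cell patient and clinical labels;
* cell × marker intensity tables with spatial coordinates from multiplex
  imaging, together with a marker × cell-type signature matrix;
* spot × cell-type proportion tables from deconvolved spatial
  transcriptomics.

`glandmap` implements that stack as composable, seeded, unit-tested
functions: QC gating, gene-index S-scoring, TACIT signature-based cell
typing, within-spot co-occurrence, Delaunay interaction graphs, and
per-patient proportion testing — plus a synthetic-data generator that
plants known ground truth so every stage can be validated without patient
data.

## QC gating

`compute_qc_metrics()` computes, per cell, the total counts, the number of
detected genes, and the percentage of counts in the mitochondrial,
ribosomal and hemoglobin gene classes. `gate_cells()` retains cells with

* mitochondrial reads < 15%,
* ribosomal reads < 50%,
* hemoglobin reads < 5%,
* ≥ 10 detected genes, and ≥ 100 total counts.

All five values are configurable through `qc_thresholds()`. The boundary
semantics are a design choice the thresholds alone do not determine: we
treat percent gates as strict upper bounds (a cell at exactly 15%
mitochondrial reads fails) and count gates as inclusive lower bounds ("a
minimum of 10 genes" reads naturally as ≥ 10). A cell with zero counts
gets 0% for every class and fails the count gate — never a division
error. Spot tables from spatial transcriptomics are gated identically.
For real data the gene classes default to the `MT-` prefix, the
`RPS`/`RPL` prefixes, and an explicit hemoglobin symbol list; synthetic
fixtures carry explicit gene lists instead so tests are prefix-agnostic.

## Gene-index S-scores

Counts are log-normalized (`lognormalize()`: per-cell scaling to a common
total, then `log1p`) and converted gene-wise to Z-scores
(`zscore_genes()`). A catalog of gene indices (gene sets; GMT files are
read by `read_gmt()`) is encoded as a binary gene × index matrix `E`, and

\[ S = Z^\top E \]

so the S-score of index *j* in cell *i* is the sum of cell *i*'s Z-scores
over the member genes of *j* (`compute_sscores()`). Two numerical
choices: Z-scores use the population SD (divide by *n*; configurable),
and zero-variance genes are kept as all-zero rows rather than dropped, so
index membership counts are preserved. Scores like a user-supplied
21-gene Type I interferon-stimulated-gene signature are one-index
catalogs (`score_ifn_signature()`); the package deliberately does not
ship index compositions — KEGG/GO/Reactome/Hallmark retrieval is the
user's responsibility. Clustering cells in S-score space is exposed only
as a comparison hook (`crosstab_clusters()`); embedding and
community-detection algorithms are published methods we do not
re-implement.

## TACIT cell-type annotation

The annotation of multiplex imaging data runs per cell type:

1. **CTR scores.** Marker intensities are z-normalized per marker
   (population SD) and multiplied by the binarized signature matrix:
   `CTR = Z × 1[signature ≥ 1]`. Signature levels ≥ 2 mark
   deeper-granularity markers (CD4/CD8 within T cells) and do not change
   scoring — they gate deconvolution later.
2. **Seed clusters.** Cells are grouped by k-means on the full
   z-normalized panel into `k = round(1/0.005) = 200` clusters, i.e.
   clusters averaging 0.5% of cells. The clustering algorithm is a design
   choice (k-means is deterministic at a fixed seed and size-controlled);
   `seed_cluster()` is the single place to plug in an alternative.
3. **Breakpoints.** For each type, the cluster-median CTR scores are
   sorted ascending and segmented linear regressions with 0–3 breakpoints
   are fitted over rank (`fit_breakpoints()`); the count is chosen by AIC
   `n·ln(RSS/n) + 2p` with `p = 2 + 2b`, ties toward fewer breakpoints.
4. **LRG/HRG.** Clusters at or below the lowest breakpoint form the low
   relevance group, clusters strictly above the highest breakpoint the
   high relevance group; clusters in between stay unassigned. A type
   whose curve supports no breakpoint is reported non-separable and its
   assignments are zeroed.
5. **Cutoff.** The CTR cutoff minimizes the cell-level LRG/HRG
   classification error, scanning midpoints between consecutive distinct
   scores; ties resolve to the lowest cutoff. Cells with `CTR ≥ cutoff`
   are marked in the binary cell-type matrix (CTM; inclusive at the
   cutoff).

Subtype columns are then AND-gated: each level-≥2 marker gets its own
positivity cutoff by the same seed-median → breakpoint → error-minimizing
machinery applied to that single marker, and a subtype is positive iff
its parent type is positive and all its level markers are positive. A
subtype's parent is identified as the signature column without level
markers whose defining set equals the subtype's level-1 set (overridable
via `parents=`).

Cells positive for several types are resolved by `resolve_mixed()`:
redundant parent bits are cleared when a subtype is set, cells positive
for exactly one type are "clean", and each remaining mixed cell is
reassigned to the majority label among its `k = 15` nearest clean cells
of the contending types, measured in the subspace of those types'
defining markers. Ties go to the single nearest neighbor — implemented
directly rather than via library KNN so the tie rule is deterministic.
The paper-scale `k` is unstated upstream; 15 is our default and exposed.
Cells passing no cutoff are `"Unknown"`.

### Breakpoint search and a known AIC limitation

The segmented fits search integer breakpoint ranks exhaustively for all
models whose combination count allows it (always for b ≤ 2 at 200
ranks); for b = 3 on long curves a coarse ~40-point grid is refined by
joint local search with a shrinking window down to step 1. On noiseless
piecewise-linear curves this recovers 1–3 planted kinks exactly, and on
curves of ≤ 60 points it matches an exhaustive `lm()`-based oracle.

AIC with adaptively optimized knot positions is *permissive about the
breakpoint count* when segments may be short: the best of ~m candidate
knot placements captures roughly `2·ln(m)` noise variance, which exceeds
the 4-point AIC penalty, so on noisy curves with a small minimum segment
length the fit tends to add spurious breakpoints (their positions remain
accurate). This matters little for cutoff derivation — extra breakpoints
only narrow the LRG/HRG groups — but it is why our Monte-Carlo
count-recovery checks constrain segments to ≥ 25% of the curve
(`min_seg = 50` of 200 ranks, matching the broad low/high plateaus these
curves exhibit in practice), at noise SD 0.5 against a slope change of
0.38/rank. At the pipeline default (`min_seg = max(3, 2%)`), count
selection under iid noise is not reliable at any signal-to-noise ratio,
and users should read the reported breakpoint count accordingly. The
converse limitation also holds: when noise dominates the slope change,
AIC selects fewer breakpoints than planted.

## Within-spot co-occurrence

Each deconvolved spot carries cell-type proportions κ summing to 1. For
two types the score

\[ C(\kappa_1, \kappa_2) = (\kappa_1 + \kappa_2)\,
   e^{-3(\kappa_1-\kappa_2)^2} \]

is high when both types are abundant *and* balanced; it is symmetric,
bounded by 2, equals `2a` on the diagonal, and for a fixed sum is
maximized at the balanced split. `spot_cooccurrence()` computes C for
every unordered type pair in every spot, averages per group, and reports
the disease-minus-control differential. Upstream the comparison was
descriptive; we attach a label-permutation p-value (1000 seeded
permutations by default) as our own design choice, so planted effects can
be judged against an explicit null. `within_spot_correlation()` and
`next_spot_correlation()` report Pearson ρ between proportion columns
within spots and between adjacent spots; adjacency is defined as spots
within 1.5× the median nearest-neighbor distance, which captures the six
neighbors of hexagonally packed spots while tolerating missing spots.

## Delaunay interaction graphs

`build_delaunay()` triangulates each tissue's segmented cells (via the
`deldir` triangulation; unlabeled/`"Unknown"` cells are excluded first,
duplicates deduplicated, degenerate tissues skipped) and keeps the unique
edges as potential interactions. `prune_edges()` removes edges longer
than the tissue's own 99th-percentile edge length
(linear-interpolation quantile, strictly-greater removal) — the
percentile is computed after Unknown exclusion. `interaction_matrix()`
counts edges by endpoint-type pair, aggregated over the tissues of a
condition, and `normalize_and_fold_change()` column-normalizes the
healthy and disease matrices and divides them elementwise; FC > 1 marks
interactions more pronounced in disease. Zero healthy denominators yield
flagged missing values rather than infinities (a `pseudocount` option
densifies when needed), and a Euclidean hierarchical-clustering order is
attached as metadata instead of rendering a heatmap.

## Proportion testing

`proportion_table()` cross-tabulates cells by patient and annotation and
row-normalizes; `test_proportions()` runs a two-sided two-sample t-test
per cell type between patient groups, then Benjamini–Hochberg correction
across all types tested in the call, flagging q < 0.05. Welch
(unequal-variance) is the default — group sizes and variances are small
and unequal in practice — with a pooled-variance toggle. Raw proportions
are tested, not transformed values.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the fixtures emulate:

* **Expression** (`synth_expression()`): negative-binomial background
  (mean 1, dispersion 0.5 — so log-normalization is meaningful),
  hemoglobin genes at mean 0.2 (clean cells must clear the strict 5%
  hemoglobin gate), 3 marker genes per type elevated by
  `1 + marker_effect`, explicit mitochondrial/ribosomal/hemoglobin gene
  lists, two balanced patient groups (`"SjD"`, `"nonSjD"`), and one
  disease-enriched type: `"Tex"` (exhausted CD8 T cells) at baseline
  frequency 0.03, enriched 4.75-fold in disease — the enrichment reported
  for this population upstream. Patient-level composition varies by a
  Dirichlet with concentration 200. QC violations are planted on
  disjoint cells, each violating exactly one rule, at configured rates.
* **Marker tables** (`synth_marker_table()`): defining markers drawn from
  `Normal(marker_effect, 1)`, all others `Normal(0, 1)`; hierarchy
  markers elevated only in the correct subtype; coordinates from
  type-clustered Gaussian blobs so neighborhood analysis has planted
  structure. `example_signature()` provides 8 leaf populations including
  a CD4/CD8-style level-2 split under a T-cell parent.
* **Spot tables** (`synth_spot_table()`): hexagonal grid with unit pitch
  (the packed-spot geometry of the platform; configurable), Dirichlet
  proportions; in the disease group a fraction of "focus" spots has the
  planted pair's concentrations jointly boosted, while the control group
  boosts the same two types in *different* spots — marginal abundances
  stay comparable, only colocalization differs.
* **Curves** (`synth_piecewise_curve()`): continuous piecewise-linear
  means over ranks with 0–3 kinks plus Gaussian noise.

All randomness flows through one seed per call, with the caller's RNG
state restored; identical configuration and seed give bit-identical
output.

What the generator does **not** emulate: ambient RNA, doublets,
segmentation artifacts, batch effects, spatially varying cell density, or
any real gland morphology. Passing tests therefore demonstrate
correctness of the computations and recoverability of planted structure —
not performance on real tissue, where marker bleed-through and
segmentation noise will lower accuracy.

## Problem sizes used in the test-suite and acceptance runs

We validate at deliberately scaled-down sizes chosen to exercise every
code path: expression fixtures of 5 patients/group × 200–500 cells with
~80–300 genes (versus ~94,000 cells upstream), TACIT recovery on 5,000
cells × 20 markers × 9 signature columns, co-occurrence on 120–200 spots
per group, breakpoint Monte-Carlo over 50 seeds on 200-rank curves, and
Delaunay oracle checks on ≤ 12-point instances over 100 seeds. At these
sizes the planted-effect checks hold with comfortable margins (TACIT
accuracy ≳ 0.94 against a 0.90 requirement; planted-pair and
planted-shift detection ≥ 80% of seeds).

## Reproducing

`run_pipeline(pipeline_config(seed = ...))` executes the stages end to
end on synthetic fixtures, writes every table as TSV plus a JSON manifest
with config and output hashes, and is byte-identical across runs at a
fixed seed. `scripts/acceptance.R --seed N --out results/acceptance.json`
recomputes the quantities above from scratch.
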