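# glandmap

Cell-type annotation and spatial interaction analysis for salivary-gland
multi-omics.

Sjögren's Disease (SjD) is an autoimmune exocrinopathy: lymphocytes
infiltrate the salivary glands, secretory (seromucous acinar) epithelium is
lost, and exhausted *GZMK*+ CD8 T cells expand and engage epithelial
targets. Quantifying that process across single-cell RNA-seq, multiplex
imaging and spatial transcriptomics requires a set of small, well-defined
computations that general toolkits do not provide. `glandmap` implements
them as composable, seeded R functions for anyone analyzing exocrine-gland
(or comparable) tissue atlases:

* **QC gating** — per-cell gates on mitochondrial (<15%), ribosomal
  (<50%) and hemoglobin (<5%) read fractions, ≥10 genes and ≥100 counts
  (`compute_qc_metrics()`, `gate_cells()`); spots gate identically.
* **Gene-index S-scores** — per-gene Z-scores of the log-normalized matrix
  multiplied by a binary gene × index encoding `E`, so
  `S = Zᵀ E` sums each cell's Z-scores over a gene set
  (`lognormalize()`, `zscore_genes()`, `compute_sscores()`,
  `score_ifn_signature()`, GMT input via `read_gmt()`).
* **TACIT cell typing** for multiplex marker tables
  (`tacit_annotate()`): Cell Type Relevance scores
  `CTR = Z · 1[signature ≥ 1]`; ~0.5%-of-cells seed clusters; segmented
  regression with up to 3 breakpoints on the ranked cluster-median CTR
  curve, selected by AIC `n·ln(RSS/n) + 2p`; low/high-relevance groups
  split at the outer breakpoints; the CTR cutoff minimizing LRG/HRG
  classification error; AND-gated CD4/CD8-style subtype refinement; and
  KNN reassignment of mixed identities among clean cells.
* **Within-spot co-occurrence** on deconvolved spot proportions:
  `C(κ₁, κ₂) = (κ₁ + κ₂)·exp(−3(κ₁ − κ₂)²)`, per-pair group differentials
  with permutation p-values, within- and next-spot Pearson correlations
  (`spot_cooccurrence()`, `within_spot_correlation()`,
  `next_spot_correlation()`).
* **Delaunay interaction graphs** — per-tissue triangulation of segmented
  cells, 99th-percentile edge pruning, type × type edge-count matrices and
  column-normalized disease/healthy fold changes (`build_delaunay()`,
  `prune_edges()`, `interaction_matrix()`, `normalize_and_fold_change()`).
* **Proportion testing** — per-patient cell-type proportions, Welch
  t-tests and Benjamini–Hochberg q-values at q < 0.05
  (`proportion_table()`, `test_proportions()`).
* **Synthetic data with ground truth** — seeded generators for expression
  matrices (with planted QC violations and a 4.75-fold disease-enriched
  type), marker-intensity tables, spot tables with planted colocalization,
  and piecewise-linear curves with known kinks (`synth_expression()`,
  `synth_marker_table()`, `synth_spot_table()`, `synth_piecewise_curve()`).

See `vignettes/glandmap-methods.Rmd` for the models, parameter choices and
known limitations.

## Worked example

Generate a synthetic cohort (5 patients per group, 500 cells each, the
exhausted-T-cell type planted 4.75-fold enriched in disease, 3% of cells
planted to violate QC), gate it, and test per-patient proportions:

```r
library(glandmap)

cfg  <- synth_config(seed = 1, qc_violation_rates = c(mito = 0.02, low_counts = 0.01))
ex   <- synth_expression(cfg)
gate <- gate_cells(ex)
gate
#> QC gate: 4850 / 5000 cells retained
#>        rule n_failed
#>        mito      100
#>        ribo        0
#>          hb        0
#>   low_genes        0
#>  low_counts       50

pt  <- proportion_table(gate$cells, type_col = "true_type", group_col = "group")
res <- test_proportions(pt, compare = c("SjD", "nonSjD"))
as.data.frame(res)[order(res$q_value)[1:2], ]
#>   cell_type mean_SjD mean_nonSjD fold_change     t  p_value q_value significant
#> 7       Tex    0.106       0.026       4.100  8.63 0.000143 0.00115        TRUE
#> 5      SMAC    0.103       0.150       0.682 -3.91 0.004461 0.01785        TRUE
```

Exactly the 150 planted violators are removed (100 mitochondrial, 50
low-count), and the planted exhausted-T expansion is recovered at 4.1-fold
(q ≈ 0.001) — its growth compresses the other populations, so the largest
acinar population drops, mirroring the seromucous loss seen in diseased
glands. Co-occurrence on a spot table with a planted Tex–SMAC
colocalization in the disease group:

```r
sp <- synth_spot_table(seed = 1)
spot_cooccurrence(sp$table, compare = c("SjD", "nonSjD"), n_perm = 1000, seed = 1)
#> co-occurrence differential (SjD - nonSjD), top pairs:
#>   type1      type2  difference     p_value
#>    SMAC        Tex  0.04679231 0.001998002
#>     Tex Fibroblast  0.03409157 0.002997003
#>     Tex         Tc  0.03053378 0.010989011
#>    ...
```

The planted pair ranks first. Cell typing of a 5,000-cell multiplex
fixture (8 leaf populations, CD4/CD8 hierarchy, marker effect 2.5):

```r
sig <- example_signature()
mk  <- synth_marker_table(synth_config(seed = 11), sig, n_cells = 5000, seed = 11)
tac <- tacit_annotate(mk$table, sig, seed = 11)
mean(tac$labels == mk$truth$true_type)
#> [1] 0.943
```

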