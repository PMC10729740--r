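# clonoscope

Quantitative tools for asking what shapes the phenotype and persistence of
antigen-specific CD8+ T cell clonotypes: the T cell receptor (TCR) sequence
itself, or the environment the cell lives in (plasma proteins, the
patient's HLA background, priming dendritic cells). The package is aimed at
computational immunologists working with longitudinal single-cell
multi-omic cohorts in which cells carry paired-chain TCR sequences,
transcriptomes and surface-protein counts across infection timepoints.

## What it implements

* **Paired-chain clonotype distance** — a TCRdist-style semimetric: summed
  per-position BLOSUM62 penalties `min(4, 4 - BLOSUM62(a, b))` over the
  germline CDR1/CDR2/CDR2.5 loops (weight 1) and the trimmed CDR3 of each
  chain (weight 3), with a central gap block (penalty 4 per position,
  weighted) for unequal lengths.
* **Clonotype graph and clusters** — PCA of the distance rows, adaptive
  Gaussian kNN graph, Leiden clustering at the highest resolution (0.01
  grid) that leaves no cluster below a minimum size, plus a UMAP view.
* **Sequence similarity between clusters** — diffusion components of the
  clonotype graph; for clusters A and B the score
  `s(i) = mean_dpt(i, roots in B) - mean_dpt(i, roots in A)` is positive
  when clonotype `i` is sequence-closer to A; binned association relates
  the score to any per-clonotype variable.
* **Phenotype layer** — ln(1+CPM) normalization, one-vs-rest Mann-Whitney
  marker genes with BH adjustment, Ward/silhouette co-expression modules,
  mean-expression signature scores, per-batch signature standardization,
  background-relative (isotype) surface-protein z-scores, and
  mass-conserving kNN density diffusion on embeddings.
* **Persistence layer** — per-draw repertoire percentages; per-cluster
  contraction strength `C = log10(mean conv % + 1) - log10(mean acute % + 1)`
  with Welch tests; screened TRAV-usage linear regression of contraction;
  reference-based contraction prediction from neighbor counts under the
  mean within-study alpha-chain distance; Kaplan-Meier splits with a
  chi-square on survival-by-arm tables.
* **Factor importance** — each omic (TCR features, plasma, HLA, cDC)
  encoded to 50 autoencoder latents (200-100-50-100-200, ReLU, Adam,
  max 25 epochs), correlated against 50 expression PCs at cell level;
  omics compared by their counts of significant correlations against the
  alpha-budgeted expectation and an equal-importance chi-square.
* **Synthetic cohort generator** — a fully labeled simulation of all of
  the above (clusters with V/J and CDR3 motif structure, four
  transcriptional programs plus cluster-private genes, low-rank
  environment blocks, per-cluster contraction kinetics), so every claim is
  testable against ground truth.

## Worked example

```r
library(clonoscope)

cfg <- cohort_config(seed = 7)        # 125 clonotypes, 25 patients, ~3,000 cells
sim <- simulate_cohort(cfg)

D  <- compute_tcrdist(sim$clonotypes) # paired-chain distances
g  <- build_tcr_graph(D)              # 30-NN graph in 20 PCs
cl <- cluster_resolution_search(g, seed = 7)
cl$resolution
#> [1] 2
table(cl$assignment)
#>  0  1  2  3  4
#> 26 25 25 25 24

freq <- clonotype_frequencies(sim$cells, sim$totals)
cs   <- contraction_strength(freq, cl$assignment)
cs[, c("cluster", "mean_acute_pct", "mean_conv_pct",
       "contraction_strength", "p")]
#>   cluster mean_acute_pct mean_conv_pct contraction_strength        p
#> 1       0           3.24         2.123            -0.132626 2.33e-05
#> 2       1           3.23         0.464            -0.461005 4.03e-22
#> 3       2           3.05         1.008            -0.304477 9.64e-16
#> 4       3           3.13         3.120            -0.000842 9.79e-01
#> 5       4           3.15         1.667            -0.192079 9.79e-10

imp <- omic_importance(sim, seed = 7)
imp
#> Factor importance (significant latent-phenotype correlations)
#>    omic n_latents n_phenotype_dims observed expected obs_minus_exp
#>     tcr        48               50      264    120.0         144.0
#>  plasma        44               50      136    110.0          26.0
#>     hla        48               50      111    120.0          -9.0
#>     cdc        45               50      121    112.5           8.5
#> equal-importance chi-square = 96.823 (df = 3, p = 7.49e-21); expected 158.0 per omic
```

Five TCR clusters are recovered at the selected Leiden resolution; their
repertoire shares fall from acute (T1/T2) to convalescent (T3) draws by
cluster-specific amounts (`contraction_strength` in log10 units, more
negative = stronger contraction), and the TCR omic shows far more
significant latent-phenotype correlations than any environment block —
the dominance the simulation plants and the framework is built to detect.

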