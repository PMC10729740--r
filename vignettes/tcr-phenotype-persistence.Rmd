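---
title: "Linking TCR sequence to CD8+ T cell phenotype and persistence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking TCR sequence to CD8+ T cell phenotype and persistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Antigen-specific CD8+ T cells that recognize the same peptide-MHC can
nonetheless differ widely in phenotype — from naive-like to terminally
cytotoxic — and in how strongly they contract after the infection resolves.
Two broad classes of explanation compete: the T cell receptor (TCR) sequence
itself, fixed at V(D)J recombination, and environmental signals (circulating
cytokines, the patient's other HLA alleles, the priming dendritic cells).
`clonoscope` implements a quantitative framework for weighing these factors
against each other in a longitudinal single-cell multi-omic cohort, together
with the sequence-space machinery the comparison rests on: a paired-chain
clonotype distance, graph clustering of clonotypes, a diffusion-based
sequence-similarity score, longitudinal contraction statistics, and a
latent-factor importance comparison.

Because patient data cannot ship with a package, every stage is exercised
against a synthetic cohort generator whose ground truth is known exactly.
The generator is a first-class module: its defaults define the package's
reference simulation, and all headline behaviors are demonstrated on it.

## The clonotype distance

Two clonotypes are compared loop by loop. The germline-encoded CDR1, CDR2
and CDR2.5 loops of each V gene enter with weight 1; the CDR3 of each chain,
trimmed of its 3 N-terminal and 2 C-terminal residues (the conserved
C...F frame), enters with weight 3, reflecting CDR3's dominant role in
antigen contact. Aligned positions are scored with the BLOSUM62-derived
penalty `min(4, 4 - BLOSUM62(a, b))` (0 for a match, capped at 4 so a
single radical substitution cannot dominate); length differences are
bridged by a central gap block costing the cap (4) per gapped position,
times the loop weight. The result is a semimetric — nonnegative, zero on
the diagonal, symmetric — but the triangle inequality is not guaranteed
and nothing downstream assumes it. An alpha-chain-only mode supports the
reference-based contraction prediction, where the alpha chain carries the
persistence signal.

Germline loop sequences for the simulated gene names are supplied by a
bundled deterministic table (`simulated_germline_table()`); tables for real
IMGT gene names can be passed by the user, and records whose V genes are
not covered fall back to CDR3-only scoring with a warning.

## From distances to clusters and embeddings

The distance matrix rows are treated as features, centered and reduced by
PCA (50 components by default; classical MDS is available behind
`method = "mds"`). A k-nearest-neighbor graph (k = 30) is built in the
leading 20 components with a locally adaptive Gaussian kernel,
`exp(-d^2 / (sigma_i sigma_j))` with `sigma_i` the distance to the k-th
neighbor, symmetrized over the union of directed neighborhoods.

Leiden community detection (modularity objective) is run along a resolution
grid (0.5 to 2.0 in steps of 0.01). "Over-clustering" is operationalized as
any cluster smaller than `min_cluster_size` (default 5 clonotypes): the
search returns the partition at the highest resolution that stays
admissible, recording the whole search path so the monotone growth of the
cluster count can be inspected. If no resolution is admissible the
start-resolution partition is returned with a warning flag. UMAP supplies
the 2-D view; for fewer than 5 points (where a UMAP neighborhood is
undefined) classical MDS is used, which is exact there.

## Sequence similarity between clusters

To ask "is this clonotype's sequence more like cluster A or cluster B?",
the graph kernel is row-normalized to a transition matrix and its symmetric
conjugate eigendecomposed; the top 15 nontrivial eigenpairs give scaled
diffusion coordinates `phi_k = lambda_k / (1 - lambda_k) psi_k`. Pseudotime
from a root clonotype is the Euclidean norm in `phi` — a diffusion distance
rather than the full branching pseudotime machinery, a simplification that
preserves all relative orderings used here. The similarity score averages
pseudotime over every root in cluster B, subtracts the average over roots
in cluster A: positive values mean "closer to A", and swapping A and B
negates the score exactly. Scores are related to external variables by
binning the score axis into 25 equal-width bins and correlating bin-mean
score with bin-mean variable (empty bins dropped; at least 3 nonempty bins
required). Bin means rather than geometric bin centers are used on the
score axis so that correlating a variable with itself gives exactly 1.

Cluster-level connectivity builds a fresh 20-NN graph in diffusion
coordinates and scores each cluster pair by observed inter-cluster edges
over the configuration-model expectation `deg_A deg_B / 2E`, clipped to
[0, 1] — an abstraction of the repertoire's cluster adjacency structure.

## Phenotype layer

Expression is normalized as `ln(1 + CPM)`. Marker genes per cluster use a
one-vs-rest two-sided Mann-Whitney U test (exact for small untied
problems, tie-corrected normal approximation otherwise) with
Benjamini-Hochberg adjustment within each label. Co-expression modules are
found by Ward clustering (on `1 - r` of the gene-gene Pearson matrix) of
the pooled top-25 markers, with the cluster count chosen by maximum mean
silhouette over k = 10..20 (ties to the smaller k; degenerate geometry
falls back to the smallest k with a warning). Signature scores are plain
means of normalized expression over the signature's genes.

Batch structure is handled by per-batch standardization of the signature
matrix — each signature column centered and scaled within each batch. This
is a deliberate, defined substitute for iterative mixture-model batch
integration: it is deterministic, exactly removes the additive batch
offsets the generator produces, and leaves the downstream correlations
unchanged in form. It will not remove nonlinear or interaction batch
effects in real data.

Surface (CITE-seq-style) proteins are normalized per cell against a set of
background (isotype-like) antibodies: `z = (ln(1+x) - mu_bg) / sd_bg`
computed within each cell; cells whose background SD is zero are flagged
and zeroed. Embedding densities are Gaussian kernel estimates of a member
set (Scott's-rule bandwidth), min-max scaled, then diffused five steps over
the row-normalized 5-NN adjacency with self-loops. Diffusion propagates
mass (`x <- t(A) x`): each cell redistributes its density over a row
summing to one, so the total is conserved to machine precision — the
contract the tests pin down. The member cell's own peak therefore spreads
into its neighborhood over iterations, which is the intended smoothing.

## Persistence layer

A clonotype's repertoire share at a blood draw is
`100 * cells / total CD8 cells` for that patient and timepoint; the
denominator can come from the cell table itself (shares then sum to 100)
or from external per-draw totals. Contraction strength per TCR cluster is

> C = log10(mean convalescent % + 1) - log10(mean acute % + 1)

with T1/T2 pooled as acute and T3 as convalescent; negative C means
contraction, and a Welch two-sided t test compares the acute and
convalescent share vectors. The formula is bounded below by
`-log10(1 + mean acute %)`: full contraction from a 9% mean acute share
gives exactly C = -1, which is why strong-contraction simulations must
place clonotypes at several percent of the repertoire during acute disease
— as strongly expanded antigen-specific clones indeed are.

TRAV (V-alpha) usage is linked to contraction by first screening each
gene's per-cluster usage percentage against C (Pearson, p < 0.05), then
fitting ordinary least squares of C on the kept usage columns plus an
intercept at cluster level (the clonotype-level alternative is exposed but
the cluster level is the default because predicted-vs-true comparisons are
cluster-level). Collinear designs are reduced by dropping the
worst-screened columns until full rank.

Reference-based prediction transfers contraction labels across cohorts
through sequence space alone: the threshold is the mean within-study
pairwise alpha-chain distance, a study clonotype's score is the number of
reference clonotypes closer than that threshold (duplicates count), and
predictions are min-max scaled to [0, 1]. Patient-level scores can be
split at a threshold and tested against overall survival with Kaplan-Meier
curves and a 1-df chi-square on the 2x2 survival-by-arm table (no
continuity correction, matching the hand-computable 5-vs-0 case of 10).

## Factor importance

Each omic block — TCR sequence features per clonotype (one-hot V/J usage,
CDR3 lengths, per-chain amino-acid composition), plasma proteins per
patient-timepoint, HLA presence/absence and dendritic-cell features per
patient — is standardized and encoded by a fully connected autoencoder
(200-100-50-100-200, ReLU, squared error, full-batch Adam at learning rate
1e-3, at most 25 epochs, early stop at relative loss change < 1e-4). The
learning rate follows the conventional Adam default; larger rates were
observed to silence most bottleneck units, and a mostly dead bottleneck
cannot represent any omic fairly. The 50 bottleneck activations per unit
are broadcast to cells, correlated (Pearson) with 50 unbiased expression
PCs (or signature columns), and each omic is scored by its count of
correlations with two-sided p < 0.05. The null expectation per omic is
`n_latents * n_phenotype_dims * alpha` — significance is deliberately
uncorrected because the expectation already budgets for alpha — and the
equal-importance null is tested by a chi-square of the observed counts
against a quarter of the total each (df = 3).

Correlations are computed at cell level after broadcasting unit latents,
the only alignment under which clonotype-level and patient-level omics
share one phenotype matrix; a unit-level aggregation is available through
the building blocks. Broadcasting inflates the effective n for every omic
alike, so the comparison stays symmetric, but two consequences should be
kept in mind. First, weak environment effects become detectable at large
cell counts, so the comparison is of counts, not of any per-test effect
size. Second, the 50 latents of a U-unit omic have rank at most U, making
significance events within an omic positively correlated; the
equal-importance chi-square is therefore anti-conservative under the
global null (its rejection rate is well above alpha in simulation), and
its p-value should be read as descriptive. The calibration property is
verified in the tests under independent full-rank latents, where the
assumption actually holds.

The plasma/PC intersection analysis correlates individual proteins with
patient-timepoint-aggregated expression PCs, Ward-clusters the rows and
columns of that correlation matrix (k by silhouette over 3..10), and for a
chosen intersection scores each patient-timepoint by the mean standardized
level of its significantly correlated proteins and each cell by the mean
of its significantly correlated PCs.

## The synthetic cohort

The generator emulates the data-generating assumptions, not any particular
dataset:

* **TCR space.** Clusters differ in dominant V/J genes (probability 0.8),
  CDR3 anchor residues (first 3, last 3 — conserved anchors in the style
  of real specificity-group motifs), preferred middle residues (used with
  probability `motif_divergence` = 0.6) and tight length distributions.
  One knob, `motif_divergence`, controls within/between-cluster
  separation.
* **Phenotype.** Four transcriptional programs (naive, memory, interferon,
  cytotoxic) with 15 module genes each; each cluster drives one program
  and additionally carries 10 cluster-private genes, making the TCR's
  transcriptomic footprint higher-rank than any environment factor's —
  mirroring the cluster-unique marker genes of real repertoires. Cell
  program activity is the weighted mixture `w_tcr * cluster loading +
  w_plasma * plasma latent + w_hla * HLA latent + w_cdc * cDC latent +
  w_noise * noise`; gene counts are negative binomial (dispersion 0.5)
  with exp-linear means.
* **Environment.** Plasma is a rank-5 factor matrix over patient-timepoints
  (only factor 1, loading an "inflammatory" protein block, couples to the
  programs — pushing interferon/cytotoxic up and naive/memory down); cDC
  features are rank-3 per patient with factor 1 coupled; HLA is a 0/1
  allele table whose weighted sum forms the patient latent.
* **Cohort design.** 25 patients x 5 clusters x 25 clonotypes, with every
  cluster represented exactly once per patient. The balance is deliberate:
  it matches the public-response structure of antigen-specific repertoires
  (about 4-5 clonotypes per patient, as in cohorts of this kind), and it
  prevents per-patient cluster composition from confounding patient-level
  omics with the TCR effect — with unbalanced assignment, any patient-level
  variable chance-correlates with cluster-driven expression through
  composition alone.
* **Kinetics.** Acute draws (T1, T2) have Poisson cell counts with mean 8
  per clonotype; the T3 mean is scaled per cluster so the expected
  contraction matches `contraction_profile` against the fixed per-draw
  repertoire size of 250 counted CD8 cells (mean acute share 3.2% per
  clonotype). Targets below the achievable floor are clamped with a
  warning.
* **Batches.** Off by default (one batch); `n_batches` and `batch_sd` add
  per-gene log-scale offsets with patients nested in batches, used to
  exercise the per-batch standardization.

What the generator does **not** emulate: realistic V(D)J recombination
statistics, thymic selection, doublets or ambient RNA, nonlinear batch
effects, clonotype sharing across patients, or any mechanistic claim about
*how* sequence determines phenotype — the linear mixing model is a testing
assumption, not biology. Passing tests demonstrate that the pipeline
recovers planted structure of the assumed form at realistic sizes, not
that real cohorts satisfy those assumptions.

## Numerical choices and degenerate inputs

Explicit seeds parameterize every random step (cohort generation, Leiden
refinement, UMAP, autoencoder initialization), and library code restores
the caller's RNG state. Ties in the silhouette-based k search go to the
smaller k; all-equal correlation geometry returns the smallest k with a
warning. Zero-total cells are excluded from normalization with a warning;
constant genes are dropped before correlation; constant features are
dropped before encoding (an all-constant block is an error); latents
constant after broadcast are skipped with the expectation denominator
adjusted. A uniform kernel density is left uniform rather than having
numerical noise min-max-amplified. Problem sizes throughout the test suite
(about 125 clonotypes and 3,000 cells for cohort-level checks, 10-100
seeds for replicated checks) were chosen as the smallest at which the
relevant statistics stabilize.

## Known limitations

* The distance is a semimetric; methods that require the triangle
  inequality should not consume it blindly.
* Per-batch standardization only removes additive, batch-constant effects
  in signature space.
* The equal-importance chi-square is anti-conservative under broadcast
  latents (see above); the observed-minus-expected counts themselves, and
  which omic is maximal, are the robust readouts.
* Leiden cluster counts are not theoretically guaranteed monotone in
  resolution; the package records the search path and the property is
  verified empirically on the graphs used here.
* The autoencoder is trained for at most 25 epochs by design; its latents
  are a fixed-budget nonlinear encoding, not a converged model, and some
  bottleneck units may stay inactive.
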