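---
title: "Detecting transition states in single-cell RNA and ATAC data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transition states in single-cell RNA and ATAC data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`scTransit` analyzes single-cell transcriptomes (and, in a parallel arm,
single-cell chromatin accessibility) of differentiating progenitors to
locate unstable *transition states* at fate bifurcations. The working
model is the attractor picture of differentiation: stable cell states
are attractors in expression space, where regulatory programs keep genes
mutually coordinated and cells tightly packed; at a bifurcation the
attractor destabilizes, coordination among program genes drops and cells
disperse. Two complementary statistics operationalize this:

- the **critical transition index** of a cluster,
  $I_C(c) = \frac{\langle |r_{g,g'}| \rangle}{\langle |r_{i,j}| \rangle}$,
  the ratio of the mean absolute Pearson correlation over marker-gene
  pairs to the mean absolute Pearson correlation over cell pairs,
  self-pairs excluded. Transition states have a **low** index.
- the distribution of **pairwise cell-to-cell distances**
  ($1 - \rho_{\text{Spearman}}$ over heterogeneous genes) within each
  cluster. Transition states have a **high** median distance.

A cluster showing both directions jointly, relative to the clusters
flanking it along the trajectory, is called a transition state.

Correlations for $I_C$ are computed on log-normalized values (Pearson),
and the cell-cell distance uses Spearman correlation for robustness to
monotone per-cell distortions. We deliberately do not standardize genes
before the cell-cell correlation: duplicated cells should have
correlation 1, which per-gene standardization would destroy. The index
is therefore invariant to gene and cell permutations and to global
affine transforms, while per-gene rescaling leaves only the gene-gene
numerator invariant. Because clusters differ in size, $I_C$ is
bootstrapped: 1000 draws of a fixed number of cells (30, or 20 for
sparser lineages) without replacement, summarized by the replicate
median.

## The RNA arm, stage by stage

**Cell QC.** Five per-cell metrics — mitochondrial percentage, features
detected with ≥ 10 counts, dropout percentage, housekeeping (Rplp0-type)
expression, percentage of genes detected — are gated at
median ± k·MAD (normal-consistent MAD, factor 1.4826; k = 1.5 or 2
depending on the metric, with the directionality each metric implies). A
cell is discarded only when it fails **more than one** criterion; this
tolerates single-metric eccentricity while removing jointly aberrant
cells. Metrics whose annotation is missing (e.g. no mitochondrial flags)
are skipped rather than silently passed; per-cell `NA` metrics count as
failures.

**Gene filtering.** A gene survives if, in at least one lineage
(excluding perturbation genotypes), its total count exceeds 2000 and
more than 10 counts are seen in at least 10 cells.

**Normalization.** Size factors come from pooled ring deconvolution:
cells are interleaved on a ring by library size, pools of 21–101
consecutive cells are summed, each pool's scale is the median ratio to
an average pseudo-cell, and per-cell factors are solved by least squares
(with low-weight library-size rows keeping the system full rank).
Factors are rescaled to mean 1; below 21 cells the estimate reduces to
library-size factors, which coincide with the pooled estimate in the
pure-depth case. Expression is `log2(count/s_i + 1)`.

**Heterogeneous genes.** The coefficient of variation and the dropout
rate both depend strongly on mean expression, so both are ordered by
mean, cut into windows of 200 genes (a trailing remainder merges into
the last window to avoid tiny-window quantile noise), z-scored within
windows, and thresholded at the within-window empirical 99th percentile
(type-7 quantile, strict inequality): on exchangeable data each
statistic selects about 1% per window. Genes with undefined CV (zero
mean) are excluded beforehand.

**Metagenes and clustering.** Scaled heterogeneous-gene profiles train a
Kohonen self-organizing map whose prototypes live in cell space, so a
tile is a *metagene*. Training is classic online SOM: 2000 epochs,
seeded random visiting order per epoch, best-matching tile by Euclidean
distance (ties to the lowest index), Gaussian grid neighbourhood. The
learning rate decays linearly 0.05 → 0.01 and the neighbourhood radius
from half the grid diagonal to 0.5; the grid defaults to roughly one
tile per two genes, capped at 8×8, always below the gene count. These
schedule values are standard for Kohonen maps; the method is robust to
them, and the final radius of 0.5 leaves a deliberate ~13% smoothing
pull between adjacent tiles. Cells-by-metagenes go through t-SNE
(perplexity 15, 2000 iterations, no PCA) and HDBSCAN (minimum cluster
size 7, min_samples 9; label −1 marks outliers). HDBSCAN is implemented
in the package (single linkage on mutual-reachability distances,
condensed tree, excess-of-mass extraction); with no `allow-single-cluster`
relaxation, a dataset with no density split comes back all-outliers,
which is the honest answer for unclustered data. At desk-scale gene
counts the 99th-percentile rule can select only a handful of genes — too
few to train a map — so the pipeline driver tops the basis up to 50
genes by within-window z-score rank; the selection thresholds themselves
are never relaxed.

**Markers.** Cluster-vs-rest AUROC from rank sums, Wilcoxon p (normal
approximation with tie correction), Welch 95% bounds on the log2
fold-change, BH adjustment within cluster. Flags: marker = AUROC > 0.8
at FDR < 0.01; differential = LFC interval clear of ±2 at the same FDR.
This rank-based ranker replaces heavier hurdle-model machinery; its
downstream consumers only need the threshold flags.

**Trajectory.** The diffusion map uses a Gaussian kernel with per-cell
local scaling (bandwidth = distance to the 5th nearest neighbour),
density normalization, and the symmetric-operator eigendecomposition;
the trivial constant eigenvector is dropped and component signs are
fixed for reproducibility. Diffusion pseudotime is the Euclidean
distance from a root cell in component space rescaled by
λ/(1−λ), min-max scaled to [0, 1]. The root defaults to a user-named
early cell (in simulations, the ground-truth earliest cell); the
analysis is insensitive to which extreme cell is chosen, up to
reversal. Perturbed cells (knockouts, overexpression) are projected by
inverse-distance-weighted k-nearest-neighbour averaging in marker-gene
space — an approximation chosen over Nyström extension for simplicity
and testability (a query identical to a reference cell inherits its
pseudotime exactly). Branches are assigned by cluster annotation, not
detected automatically.

**Gene dynamics.** A gene is pseudotime-correlated when its global
Spearman correlation with pseudotime reaches 0.7 or its within-cluster
correlation reaches 0.5 (clusters of ≥ 10 cells). Trends are smoothed by
a centered moving mean over 11 consecutive cells (windows truncate at
the boundaries; window 1 is the identity). A correlated gene is
*priming* when the mean of its smoothed trend over the early third of
the trajectory exceeds the late third (expression declining from
multipotent stages), *de novo* for the reverse; the thirds rule is our
operationalization of a verbal dichotomy.

**Cell programs.** Cell-cycle stage scores are set averages refined by
keeping genes with rank correlation > 0.4 to the raw score (refinement
can only shrink the set; if nothing passes, the raw score is kept with a
warning), then z-scored per stage. A cell is *cycling* when any stage's
scaled score exceeds 0 — the binarization is not prescribed anywhere, so
the threshold is exposed as a parameter. Proportions are compared by
Pearson χ² without continuity correction; with the published
smooth-muscle counts (138/949 vs 39/125) this reproduces the printed
p = 2.37e−6 exactly, which a continuity-corrected test does not. The
smooth-muscle classifier takes log2(TPM+1) input: Nkx2-5 below 1 and at
least 5 of the 7 panel genes (Tagln, Cnn1, Acta2, Cald1, Mylk, Hexim1,
Smtnl2) above 2, both strict.

## The ATAC arm

Cells are gated at MAD-2 on mitochondrial content (upper), accessible
peaks and log-scaled total counts (two-sided), same more-than-one-failure
rule. Peaks must be open in more than 35 cells with mean count below 15.
Counts are binarized and TF-IDF weighted with `tf = x/total accessible`
and smoothed `idf = log(1 + N/(1+df))` — a form that stays finite and
positive at full occupancy. SVD reduces to 50 dimensions; the first
component is excluded before t-SNE (perplexity 21) and HDBSCAN (11/9).
The exclusion is empirical: on simulated accessibility with a ~20-fold
depth spread, component-1 cell scores correlate with log accessible-peak
counts at |r| ≈ 0.91, and depth explains ~80% of the component's
variance against ~6% for cluster identity. (The relation is concave, so
the correlation is diagnosed on the log scale, matching the log-scaled
depth metric used in QC.)

Cluster-specific peaks use a one-sided hypergeometric test per
peak × cluster on binarized accessibility with BH adjustment across
peaks; each significant peak (adjusted p < 1e-5) is assigned its
lowest-p cluster. This replaces an empirical-Bayes regression test while
preserving the downstream contract — a peak→cluster assignment set.

Motif deviations follow the chromVAR recipe: expected accessibility of
cell *i* in a motif's peaks is the cell's depth times the summed
expected peak fractions; the raw deviation is the relative
observed-minus-expected; 50 background peak sets matched on
expected-accessibility deciles (GC matching is not applicable to
coordinate-free synthetic peaks and is accepted as an optional column)
standardize it into a Z-score. Background sampling is seeded per motif
from the motif's peak content, so identical motifs receive identical
backgrounds within a call. Null motifs come out approximately standard
normal (|mean| ≈ 0.01, sd ≈ 1.0 across cells).

RNA:ATAC pairing mean-centers TF expression, smooths it over 15 ordered
cells (13 for deviation trends), resamples to a common grid, and scans
signed cross-correlation over lags up to 25% of the trajectory; a best
lag within 5% is `matched`, positive lags are `rna_precedes`, negative
`atac_precedes`. Pairs whose best correlation stays under 0.3 are
low-confidence — maximizing the signed rather than absolute correlation
keeps anti-correlated pairs from producing confident lag calls. The lag
thresholds are configurable operationalizations of a verbal
matched/precedes dichotomy. Peak–TSS annotation is proximal at
|distance| ≤ 2.5 kb from the peak midpoint (the literature also uses
5 kb for some purposes; the threshold is a parameter).

## What the generators emulate — and what they do not

- `generate_rna_counts`: negative-binomial counts (dispersion 0.1) for
  2000 genes × 300 cells in 5 clusters, 10% of genes differential per
  cluster at |log2 FC| = 2, library sizes 20k–100k, and Bernoulli
  dropout with probability logistic-decreasing in the log mean
  (`p = 1/(1+exp((log μ − 1)/0.5))`) — the mean–dropout relation the
  feature selector exploits. A 2% block of mitochondrial genes and one
  high housekeeping gene make QC exercisable.
- `generate_trajectory_counts`: 1000 genes × 300 cells in five
  pseudotime bins (two pre-branch, one straddling the branch point at
  0.5, two post-branch arms). 30% of genes carry sigmoidal programs of
  pseudotime; 10% per arm are arm-restricted; 20 strong linear
  "reporter" genes track pseudotime cleanly. A shared latent factor
  (loading sd 0.6) couples the non-reporter program genes within every
  cell; transition-cluster cells have this loading multiplied by
  `coordination_drop` (0.5) and their NB dispersion multiplied by
  `noise_inflation` (3). The coordination module sits on the program
  genes themselves because those are the genes whose mutual coupling a
  destabilized state loses; placing it elsewhere leaves the gene-gene
  numerator at its sampling noise floor and the signature inverts.
- `generate_atac_counts`: 5000 peaks × 400 cells, 5 clusters, 20% of
  peaks cluster-specific (8-fold boosted at home, 50-fold suppressed
  elsewhere), multinomial reads per cell (depth uniform in 200–800, so
  column sums are in range by construction and > 90% of entries are
  zero), with 60% of reads following the cluster signal profile and the
  rest uniform background. 50 motifs hit peaks at 5% density; one motif
  per cluster is planted at 5× density in that cluster's specific peaks.
- `generate_cellcycle_fixture`: five stage sets of 20 genes; cycling
  cells overexpress one stage (+2 log2 units, half-strength spillover
  onto the next stage).

All generators run on their own seeded RNG stream and restore the
caller's RNG state; identical configs give bit-identical output. They do
**not** model batch effects, doublets, read-level error, fragment
chemistry, GC content, or realistic gene-gene network topology — so
passing recovery tests demonstrates that the algorithms do what they
claim under their stated assumptions, not that real datasets will be as
clean. Conversely the planted effect sizes are deliberately moderate:
the transition signature is detected through the full pipeline, not read
off the truth labels.

## Numerical choices and degenerate inputs

- MAD gates with zero spread flag nothing (all-identical metrics keep
  every cell); thresholds are refused below 5 cells.
- All-zero cells are an error for size factors and TF-IDF (named in the
  message); zero-variance genes/cells are dropped with a warning before
  correlation work; all-constant matrices give `NaN` with an error flag.
- Quantile convention is type-7 throughout; BMU and nearest-neighbour
  ties resolve to the lowest index; diffusion component signs are fixed
  by the largest-magnitude entry.
- Per-stage seeds derive from the global seed plus a stage-name hash,
  kept below 2³¹, so pipeline stages are individually reproducible.

## Evaluation problem sizes

The shipped checks run: the transition signature over 100 simulated
bifurcations (bootstrap 100 replicates — the analysis default of 1000 is
unchanged, the evaluation uses fewer); clustering recovery over 20
datasets per arm; motif direction recovery over 100 datasets (planted
motifs only); null calibration over 3 datasets × 10 null motifs; and a
full two-arm pipeline determinism run at 600 genes × 200 cells (RNA) and
2000 peaks × 300 cells (ATAC). These sizes keep the whole evaluation
around a quarter hour on one CPU while leaving every threshold at its
analysis default.

## Known limitations

- HDBSCAN returns all-outliers on data with no density split (no
  single-cluster mode); continuous trajectories therefore cluster into
  pseudotime segments only where density dips.
- The SOM final neighbourhood radius (0.5) leaves a small cross-tile
  smoothing bias on very small grids.
- kNN projection cannot extrapolate beyond the reference manifold;
  query cells from unseen states land on the nearest seen state.
- One documented discrepancy in the underlying procedure: the
  correlated-gene rule is stated once as global ≥ 0.7 / local ≥ 0.5 and
  once as a single 0.5 cutoff; the two-threshold rule is implemented.
- The pooled deconvolution clips non-positive solutions to library-size
  estimates with a warning rather than iterating.
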