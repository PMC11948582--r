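---
title: "Methods: spatial metrics, neighborhood topics, and the discovery–validation survival framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial metrics, neighborhood topics, and the discovery-validation survival framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`spatmark` analyses single-cell tables derived from multiplex tissue images
(CycIF, IMC, MIBI): phenotyping, per-sample spatial statistics, neighborhood
topic models, and a discovery–validation screen of spatial metrics as
survival biomarkers. This vignette records the models, their assumptions,
the parameters that matter, and the design decisions taken where a published
procedure leaves the details open.

## Coordinate and distance conventions

Cell positions are nuclear centroids in micrometers, origin at the field's
top-left corner with y increasing downward (image convention). Every radius
query is Euclidean and inclusive (`d <= r`). These conventions make every
oracle test unambiguous: a pair at exactly 40 μm is a neighbor at radius 40.

## Image features

* **Hot pixels.** A pixel is hot when it exceeds the 2×2-kernel
  median-filtered image by more than 10 standard deviations; hot pixels are
  replaced by the median-filter value. The SD is taken over the *residual*
  image (image minus its median filter) across the whole field: the rule is
  stated in SD units without naming the reference distribution, and the
  global residual SD is the standard reading; it also makes the operation
  idempotent on our planted-spike fixtures. The even 2×2 window is anchored
  with the target pixel at its top-left corner and clipped at the border.
* **Autofluorescence.** `img − af · (exposure_img / exposure_af)`, clipped
  at zero. Both exposure times are required; there is no silent default.
* **Segmentation input.** Cytoplasmic channels are combined by per-pixel
  maximum; each channel is clipped to
  `[q(clip_low_q), clip_high_factor · q(0.99999)]`, min–max rescaled,
  gamma-adjusted (`x^γ`, with γ ≈ 0.6 for MIBI-style and 0.4 for IMC-style
  data) and Chambolle total-variation denoised (weight 0.1; 0.05 for
  IMC-style cytoplasm). The low clip is parameterised as a quantile
  (default 0.03) because the upper clip is quantile-anchored and the lower
  bound's units are otherwise undefined. A constant image is clamped into
  [0,1] and passed through the gamma map unchanged — the degenerate rescale
  is defined so that the TV fixed point is preserved.
  TV uses Chambolle's dual projection (step 0.25, ≤100 iterations,
  tolerance 1e-4 relative).
* **Mask algebra.** Cell objects are relabeled to the nucleus they overlap
  most (ties → lower nucleus id); cells with no nuclear overlap are dropped;
  a nucleus claimed by several cells keeps the largest-overlap cell (ties →
  lower original cell id). Cytoplasm = cell pixels minus *all* nuclear
  pixels, so a foreign nucleus protruding into a cell is never counted as
  that cell's cytoplasm. Eccentricity uses the second central moments of the
  nucleus pixel set (the standard region-property definition, with the
  1/12-pixel variance correction so single rows do not degenerate).
* **QC.** Per-marker `{lower, upper}` clamps implement aggregate/background
  artifact handling; thresholds are configuration inputs because no
  universal values exist. The estrogen-receptor image QC — originally a
  blinded human sort — is a documented automated stand-in: a sample passes
  when at least a configurable fraction of its epithelial nuclei exceed an
  ER threshold and this agrees with the clinical ER status.

## Phenotyping

Features are scaled by dividing each column by its SD (computed over
non-excluded cells) *without centering* and clipping above 20 SD; nuclear
area (and eccentricity for panels that use it) is appended and scaled the
same way. Cells are clustered on a symmetric 30-nearest-neighbor graph with
Leiden (modularity objective); the resolution is found by bisection on
[0.01, 3] (≤25 iterations) until the cluster count lands in the target range
(20–25 by default); if no resolution achieves it, the closest partition is
returned with a warning.

Gating assigns exactly one lineage per cell. Multi-positive cells are
resolved by precedence **epithelial > immune > endothelial > fibroblast**
(configurable): the stromal definition ("none of the above") already implies
the four positive lineages outrank stroma, and epithelial misassignment is
the most consequential for tumor-anchored spatial metrics, so epithelial
claims first. Gate thresholds are configuration inputs with fixture
defaults; the published per-marker values are not available.

## Patient subtyping

Per patient, counts are pooled over all cores *before* fractions are taken
(the pooling rule is not published; summing counts weights cores by cell
number and is invariant to splitting a core in two). Rare types below 4 %
(epithelial) or 2 % (stromal) of the pooled cohort compartment are dropped.
Fractions are Z-scored within platform, and patients are Leiden-clustered.
"Minimise differences between the platforms" is given a concrete objective
here: among partitions whose cluster count lies in a configured range, pick
the one minimising the platform-association χ² statistic. Stromal mode scans
resolutions upward and returns the first partition in which some cluster's
top-enriched type is the T-cell type.

## Spatial statistics

All statistics operate on non-excluded cells and are written to be checkable
against O(n²) enumeration — the test suite does exactly that on ≥20 random
fixtures.

* **Neighbor counts** (40 μm) and the **mixing score** (25 μm;
  tumor–immune edges / immune–immune edges; zero denominator → flagged
  missing with a reason rather than ±Inf).
* **Isolated lymphocytes** (20 μm): tumoral ⇐ ≥1 epithelial cell within
  20 μm; isolated ⇐ fewer than 5 lymphocytes (self excluded) within 20 μm.
  The lymphocyte set defaults to CD3 T and CD20 B cells.
* **Occupancy AUC** (grids of 10–300 μm in 10-μm steps, anchored at the
  field origin): occupancy(s) = boxes with ≥1 tumoral lymphocyte / boxes
  with ≥1 cell of any type; the denominator is a cell-derived tissue proxy,
  chosen because no tissue mask exists in a point table. The AUC is the
  trapezoidal integral normalised by the size range, hence in [0,1].
* **Fractal dimension**: least-squares slope of log(occupied boxes) vs
  log(1/s). The reported *difference* is FD(tumoral lymphocytes) −
  FD(tumor cells) on identical grids — the tumor set as reference
  normalises for tissue geometry. Eligibility requires tumoral lymphocytes
  and at least 3 occupied 10-μm boxes (the intact-tissue guard). Grid-
  anchored statistics are origin-dependent by construction; tests bound the
  sensitivity to a half-box origin shift rather than assuming it is zero.
* **Ripley's L and cross-type K/G** (50 μm): translation edge correction on
  rectangular windows, with the unbiased `n(n−1)` (or `n_a n_b`) intensity
  estimate; K is reported on the L scale, `sqrt(K/π)`, so CSR has
  expectation r. Gcross is the uncorrected empirical nearest-neighbor CDF —
  the reduced-sample caveat applies and is accepted for a fixed small r.
* **Voronoi interactions**: adjacency = Delaunay edges (computed by an
  in-package Bowyer–Watson triangulation) capped at 100 μm to remove hull
  artifacts; the statistic is the number of positive–positive adjacent pairs
  divided by the number of positive cells. Exactly cocircular quadruples
  are resolved by insertion order; either diagonal is a valid triangulation.

## Neighborhood topic model

Documents are per-tumor-cell counts of non-epithelial cell types within
100 μm (inclusive); all-zero documents are kept but flagged. The model is
latent Dirichlet allocation fit by variational EM with priors α = 1/K on
document–topic proportions and η = 0.1 on topic–type weights, K = 8 by
default. Convergence: ≤100 EM iterations or 1e-4 relative change in the
likelihood proxy; ≤30 inner E-step iterations.

Spatial coupling replaces the reference implementation's ADMM-regularised
formulation with a neighbor-mean shrinkage: at each E-step the variational
document–topic posterior is blended toward the mean posterior of the
anchors within the document radius with weight `coupling/(1+coupling)`
(default coupling 0.1; 0 recovers standard LDA exactly). The intent —
adjacent tumor cells share topics — is the same; the inference is simpler
and the weight is exposed. Held-out perplexity is reported on a 10 %
document fold-in. Topic labels are only identified up to permutation, so
all recovery tests match by exhaustive permutation on cosine similarity.

Neighborhoods are K-means clusters (k-means++ seeding, fixed seed) of the
anchor × topic matrix; a direct K-means on row-normalised count documents is
provided as the comparator surface.

## Survival framework

* **Binarisation**: within each platform × subtype stratum, high ⇐ value
  strictly above the stratum's q-quantile (linear-interpolation quantile,
  R type 7); ties at the cutoff are low. The quantile definition and tie
  rule are not published; both are frozen here and tested (all-equal values
  ⇒ all low).
* **Discovery**: for each metric, log-rank p at q ∈ {0.33, 0.5, 0.66};
  metrics with min p < 0.05 are kept with the arg-min quantile (exact ties →
  0.5, the median cutoff). The min-of-three selection is deliberately
  uncorrected — the optimism stays on the discovery side and the tests
  verify the inflated null retention rate there.
* **Validation**: frozen cutoffs applied within validation strata; BH
  adjustment over the candidate family per endpoint × subtype (the family
  definition is not fully published; per endpoint × subtype is this
  package's documented choice, exposed in the study config). Significance
  at FDR < 0.05, relaxed to 0.1 for neighborhood metrics. Discovery and
  validation patient sets are verified disjoint; overlap aborts.
* **Confirmation**: Cox proportional hazards on biomarker-high + age +
  tumor size + stage, stage ordinal numeric by default (configurable to
  categorical). Incomplete cases are dropped and counted; constant
  covariates and separation (infinite or absurdly large coefficients) raise
  errors with diagnostics rather than returning unstable estimates. Any
  log-rank test requires ≥5 patients and ≥3 events per arm.

## The synthetic-data generator

The generator emulates TMA cores as bounded 2-D point patterns: tumor nests
as discs, per-type densities of the order of one cell per ~20 μm square,
uniform-Poisson or Thomas-cluster placement (Poisson parents, Gaussian
offspring — a fixture choice, not a claim about tissue), lognormal
type-conditional intensities (background median 1, positive median =
`separation`, default 10×), and exponential proportional-hazards survival
with administrative-plus-dropout censoring (censoring 0 ⇒ all events).

The planted tumor–immune mixing dial acts through two monotone mechanisms:
an exclusion buffer of 25·(1−m) μm around tumor cells for non-attracted
immune cells, and an attracted fraction m/2 re-placed around random tumor
cells with a 15-μm Gaussian kernel. At m = 0 this guarantees complete
separation (no tumor cell within 25 μm of an immune cell); the attracted
kernel is deliberately wide so that packing immune cells near tumor does not
inflate the immune–immune edge count and break monotonicity of the mixing
score.

Rendered images draw each cell as a nucleus disc inside a cell disc;
channels are painted in two passes (all cytoplasm discs, then all nucleus
discs) in cell-id order so that overlapping discs remain bit-consistent with
the label masks — at zero noise, feature extraction reproduces the
generating intensities exactly. Hot pixels are planted at values far above
any tissue signal so the detection rule must find exactly them.

What the generator does **not** emulate: real marker covariance structure,
segmentation errors, staining gradients, batch effects, 3-D tissue, or the
marginal distributions of any real cohort. Passing tests therefore
demonstrate correctness of the algorithms under known truth, not
performance on real images.

Cohort simulation realises one small tissue per patient (with lognormal
per-patient density multipliers, σ = 0.5 on the log scale, and a uniform
mixing level), computes the metric panel (per-type fractions and the mixing
score) from the realised tissue, and draws survival from an exponential
model whose linear predictor sums the planted log hazard ratios over
metrics above their cohort median. Because the hazard acts on the
*realised* metric, discovery power reflects the whole pipeline, not just
the survival model.

## Problem sizes and runtime choices

The test suite exercises: oracle equivalence on 20 random tissues of 50–300
cells; CSR calibration of L(50) over 200 fields of ≈1000 points; the mixing
dial at 5 levels × 10 seeds; occupancy dispersion over 100 paired seeds;
topic recovery at 2000 anchors; framework power over 15 simulated
three-platform cohorts of 300 patients (150 discovery / 150 validation) and
null calibration over 15 cohorts of 150 patients; CPH recovery over 100
simulated cohorts of n = 300. These sizes were chosen so the full suite
runs in a few minutes on a single core while keeping every binomial
acceptance band meaningful.

## Known limitations

- Gcross is uncorrected; for radii approaching the field size it is biased.
- The kNN graph is built by exact blockwise distances (no approximate
  neighbor search), which is the right trade-off for ≤10⁵ cells per sample.
- The spatial-LDA coupling is a shrinkage heuristic, not a generative
  spatial prior; its strength is a tuning parameter with default 0.1.
- Leiden partitions depend on the RNG seed; all entry points take and set
  seeds, and determinism at fixed seed is tested, but different igraph
  versions may yield different (equally valid) partitions.
- The occupancy denominator (boxes containing any cell) under-counts tissue
  in very sparse samples; the intact-tissue guard exists for that reason.
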