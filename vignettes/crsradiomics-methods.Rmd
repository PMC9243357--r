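---
title: "Methods: radiomic prediction of chemotherapy response score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic prediction of chemotherapy response score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`crsradiomics`: the model and its assumptions, the tunable parameters,
what the synthetic generators do and do not emulate, and the known
limitations of the procedure.

## The prediction problem

Patients with advanced high-grade serous ovarian carcinoma treated with
neoadjuvant chemotherapy are graded after delayed surgery by the
chemotherapy response score (CRS) of their omental tumor deposits. The
package predicts the dichotomized score — complete response (CRS3,
label 1) versus non-complete (CRS1–2, label 0) — from the pre-treatment
CT appearance of the segmented omental lesions. The clinically relevant
asymmetry is that reliable identification of *non-responders* (high NPV)
matters most, and that external cohorts can be strongly imbalanced
(about one positive in five), which motivates G-mean and NPV as primary
metrics rather than accuracy alone.

## Feature extraction

### Resegmentation and quantization

Intensity and texture features are computed on the voxels of the manual
mask whose intensity lies inside a closed resegmentation range, default
[−100, 400] HU. This removes fatty/cystic/necrotic (hypodense) and
calcified (hyperdense) material so texture is measured on soft tissue.
Gray levels are obtained with the Freedman–Diaconis rule,
`width = 2·IQR·n^(−1/3)` HU on the resegmented lesion voxels, and level
`floor((v − min)/width) + 1` capped at `ceiling((max − min)/width)`
levels. Two choices deserve note:

* **Bin anchoring.** Bins are anchored at the per-lesion minimum, not at
  the fixed range lower bound. The FD rule is per-sample by nature; an
  anchored variant can be obtained by passing a fixed `bin_width` and is
  the only alternative a fixed-range anchor would affect.
* **Degenerate IQR.** For near-constant lesions the FD width collapses;
  a fallback width of 25 HU (configurable) is used, giving a single
  level and degenerate (but well-defined) texture values.

Voxels are never resampled: features are computed at the original voxel
sizes. Texture neighborhoods are grid-step neighbors (26-neighborhood,
13 unique directions at distance 1 voxel), so anisotropic spacing enters
only through physical-coordinate shape computations — the common
convention when no resampling is performed.

### Shape features

The 14 shape descriptors use two geometric constructions:

* an **iso-surface mesh** of the mask at the 0.5 level, built by
  marching tetrahedra (each surface cell split into six tetrahedra,
  crossings at edge midpoints since corners are binary). The mesh is
  closed and consistently oriented, so the divergence theorem gives the
  enclosed volume; surface area is the triangle-area sum. A tetrahedral
  surface is slightly rougher than a table-based marching-cubes surface:
  mesh volumes agree with analytic ellipsoids to a few percent at
  typical lesion sizes (verified in the test suite), while surface area
  (hence sphericity) carries a modest systematic jaggedness that is
  consistent across lesions and therefore harmless for comparative
  modeling.
* **principal axes** from the eigen-decomposition of the sample
  covariance of mask-voxel physical coordinates: axis lengths
  `4·sqrt(λ)`, elongation `sqrt(λ2/λ1)`, flatness `sqrt(λ3/λ1)`. Note
  the formula direction: elongation equals 1 for an equant (sphere-like)
  lesion and *decreases* as the lesion becomes more elongated; the
  package implements the conventional formula and leaves directional
  interpretation to the analyst.

Maximum 2D diameters are the largest pairwise surface-vertex distances
within planes named by the fixed axis under the (slice, row, column)
convention: the "column" diameter lives in the plane spanned by the
slice and row axes (the coronal plane for axial acquisitions).

### Texture conventions

GLCM and GLRLM features are computed per direction (13 unique 3D
directions, distance 1, symmetric GLCM) and averaged without weights.
Zones (GLSZM) use 26-connectivity; dependence (GLDM) counts the voxel
itself plus equal-level 26-neighbors (tolerance 0), so dependence is at
least 1; gray-tone differences (NGTDM) use the mean of valid in-mask
26-neighbors, excluding voxels with no valid neighbor. All entropies are
base-2 with an additive `1e−16` inside the logarithm, so single-level
degenerate cases give exactly interpretable values (e.g. IDMN 1,
difference entropy 0 for a constant lesion).

## Modeling

### Nested cross-validation and leakage control

The estimator is Elastic Net logistic regression (glmnet backend),
`mean binomial deviance + λ(α‖β‖₁ + (1−α)‖β‖₂²/2)` with an unpenalized
intercept, fitted on z-scored features. The mixing parameter α defaults
to 0.5 — only λ is tuned, and an equal L1/L2 mix keeps grouped selection
of correlated features while still producing sparsity; α is exposed in
`elastic_net_config()`.

Evaluation uses a nested 5 × 5 cross-validation repeated (default 100
times) over random permutations of the cohort, yielding
`k_outer × n_repetitions` fitted model instances. Every supervised
decision is made strictly inside the training side of each split:

* the redundancy filter (Spearman |ρ| ≥ 0.90 → drop the member with the
  lower univariate AUC) reads the labels, so it runs inside the inner
  loop on inner-training rows, and once more on the full outer-training
  partition for the deployed model;
* z-score parameters come from the same training rows;
* λ minimizes the mean inner-validation deviance over a shared
  descending log grid (100 values, dynamic range 10³), ties resolved to
  the larger (more parsimonious) λ;
* the decision threshold τ maximizes the G-mean of the pooled
  inner-validation predictions over midpoints of the sorted unique
  scores, ties to the smallest candidate. G-mean was chosen as the
  threshold criterion because the evaluation emphasizes
  imbalance-robust metrics; it is one defensible reading of
  "optimized decision threshold", not the only one.

Each outer-fold model is refit on its full outer-training partition
after inner selection (standard nested-CV practice, maximizing the data
behind each deployed model), rather than promoting the best inner-fold
model. Stratified fold assignment is the default: with 21–41%
positives, unstratified 5-fold splits easily produce single-class folds.

Under permuted labels the pooled outer AUC is, if anything, slightly
*below* 0.5: cross-validation is mildly pessimistic under the null
because chance in-sample associations reverse on held-out folds.
Leakage through the supervised filter would push it above chance, which
is what the calibration test checks one-sidedly; the band
[0.45, 0.55] is verified by the acceptance suite with labels
re-permuted at every repetition.

### Stability selection and the signature

A feature's occurrence count is the number of model instances with a
non-zero coefficient for it; features above a strict fraction of the
instance count (default 0.6, i.e. more than 300 of 500) plus the
forced-in whole-tumor volume form the reduced signature, which is refit
with *identical* data partitions (same derived seeds) and the redundancy
filter disabled. Coefficient averages are reported under two
conventions — over all instances (absent = 0; the default) and over
selecting instances only — because the choice is not canonical.

For synthetic cohorts that contain deliberate blocks of rank-correlated
copies, the filter may retain a different block member per instance,
splitting one signal's count across column names. The helpers
`block_occurrences()` / `block_mean_coefficients()` collapse the
analysis to blocks (a block occurs when any member is non-zero); the
parameter-recovery acceptance checks operate at block level for this
reason. Without such designed redundancy the per-feature and block
analyses coincide.

### Ensemble and external evaluation

The deployed classifier for an external cohort is the ensemble of the
five outer-fold models from one designated repetition, each member
standardizing with its own parameters and voting at its own threshold;
an odd member count makes ties impossible. The continuous score for AUC
is the mean member probability (vote fraction is available as an
alternative). Metrics with empty denominators (e.g. NPV of a classifier
that never predicts negative) are reported as `NA`, never coerced to 0,
so dispersion summaries stay honest; in baseline comparisons such a
baseline cannot be counted as beating the ensemble.

## What the synthetic data emulate — and what they do not

`generate_feature_cohort()` produces independent standard-normal
informative features with specified log-odds effects, labels from a
logistic model whose intercept is root-solved so the expected positive
rate hits the target prevalence (0.41 discovery / 0.21 external by
default, n = 61 / 48), redundant copies as rank-preserving perturbations
calibrated to a target Spearman ρ, and independent noise. The defaults
for effect size (|β| = 1) and block correlation (0.95) were fixed once
as a realistic moderate-signal regime and are not adjusted per
experiment.

`generate_lesion_phantom()` builds ellipsoidal lesions filled with a
stationary Gaussian random field (white noise smoothed at a 3 mm
correlation length, mean 60 / SD 20 HU) plus compact hypodense
(−160 HU) and hyperdense (+600 HU) inclusions on a fat-like −90 HU
background, so sub-segmentation, resegmentation and texture all have
signal to act on. Responder phantoms shrink the least semi-axis (factor
0.6 by default), encoding the direction that responders present more
elongated lesions with smaller least axis.

Passing tests on these data show that the *pipeline machinery* is
correct — leakage-free selection, calibrated null behavior, recovery of
planted effects, imbalance handling. They do not show that real omental
radiomics carries the signal: the phantoms have no CT physics (noise
spectra, beam hardening, scanner variation), no multi-lesion anatomy,
and Gaussian feature distributions without the heavy tails and
inter-feature dependencies of real radiomics. Patient-data results
(specific AUC levels, the identity of the selected clinical signature)
are not reproducible from synthetic data and are not claimed.

## Numerical choices and problem sizes

* Sample (n−1) standard deviations in z-scores; population moments in
  first-order skewness/kurtosis/variance (kurtosis not
  excess-corrected); type-7 quantiles throughout.
* Redundancy uses |ρ| (anti-correlated duplicates are equally
  redundant) with average-rank ties; the greedy order removes the
  strongest pair first and all tie-breaks are lexicographic, making the
  filter fully deterministic.
* The robustness (ICC) filter is off by default: it stands in for a
  feature-calibration step whose exact original procedure is not
  reproducible here, using a two-way agreement ICC (threshold 0.75)
  between original and perturbed-mask extractions.
* Every random draw derives from a base seed through integer mixing of
  (stage, repetition, fold), so any repetition can be reproduced in
  isolation; all derived seeds stay below 2³¹.
* Test and acceptance problem sizes were chosen to exercise the study
  design at desk scale: phantoms of ~40³ voxels (feature extraction a
  few seconds per lesion), the full 100 × 5 instance count at n = 61,
  recovery runs at n = 200 with 42 features and 10 repetitions × 20
  seeds, ensemble comparisons at n = 61/48 with 20 seeds.

## Known limitations

* The marching-tetrahedra surface overestimates area relative to
  smoother meshers; sphericity and surface-to-volume ratio are
  internally consistent but not interchangeable with other
  implementations' values.
* The dependence-count convention (center voxel included) and the
  per-lesion bin anchoring are documented choices among several in use;
  comparing absolute texture values across software requires matching
  these conventions.
* Occurrence-count stability selection is a heuristic: at small n it
  admits noise features alongside true signals (visible in the README
  demo at n = 61), and its threshold (0.6 of instances) is a convention,
  not an inferential guarantee.
* Whole-mask texture is the default analysis surface; sub-segmented
  (soft-tissue-only) texture is available via `subsegment_tissue()` +
  `resegment()` but the two agree strongly on lesions whose inclusions
  are small, and only the whole-mask route is exercised end to end.
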