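---
title: "Dynomics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynomics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: what is
computed, under which conventions, which parameters matter, and which
design decisions were genuinely open. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The dynomics idea

A dynamic PET acquisition is a 4D record: a 3D activity volume per
timeframe, with a schedule of frame start times and durations. Static
radiomics extracts a feature panel from one late-time image (here: the
voxelwise mean of the last five timeframes, the convention for this
acquisition protocol). Dynomics extracts the same panel *within every
frame*, producing a feature-by-time matrix per VOI, and condenses each
feature's trajectory into two robust summaries:

* temporal median — a noise-robust central value of the trajectory, and
* temporal MAD, `median(|f_t - median(f)|)`, unscaled (no 1.4826
  Gaussian consistency factor; the plain median absolute deviation is
  what the summary's name promises, and no downstream step assumes a
  Gaussian calibration).

The median and MAD blocks are concatenated into an `n x 2m` design
matrix. The scientific claim this operationalizes: lesions whose
subregions have heterogeneous kinetics change their spatial texture over
the acquisition, so temporal summaries of texture separate
response classes even when late-time (static) images do not.

## 2. The 107-feature set

Exactly 107 features per VOI, in a frozen canonical order:
18 first-order + 14 shape (3D) + 24 GLCM + 16 GLRLM + 16 GLSZM +
5 NGTDM + 14 GLDM. The roster follows the standard feature set of the
dominant open-source radiomics engine; a 2D shape family cannot be added
without exceeding 107 for a 3D mask, and the first-order family keeps
Variance but not StandardDeviation (the standard 18-entry set).

**Discretization.** All texture families operate on gray levels.
Default: `fixed_bin_count` with 32 bins over the in-mask min–max range.
For dynamic series each frame is discretized independently — the frame's
own min/max span the bins. This choice matters: it makes texture
features invariant to pure intensity scaling, so a lesion whose spatial
pattern is constant while its amplitude follows one uptake curve has
(noise aside) *time-constant* texture, and temporal MAD isolates genuine
pattern change. A `fixed_bin_width` mode and a pooled-range
(`global_discretization`) flag are available for parity with common
radiomics defaults. Nothing in the extraction resegments the mask or
resamples the grid; GLCM distances are in voxels.

**Degenerate-case conventions** (all frozen, all tested): `0·log2(0) = 0`
everywhere; Skewness and Kurtosis of a constant region are 0; GLCM
Correlation and MCC are 1 when a single gray level is present; NGTDM
Busyness and Strength are 0 when their denominators vanish and
Coarseness is capped at 1e6; a VOI with no neighboring voxel pairs falls
back to self co-occurrence of the level histogram (so single-voxel masks
yield Contrast 0, JointEnergy 1). GLDM dependence size is the count of
26-neighbors within `alpha` of the center level *plus one*, so isolated
voxels occupy the smallest dependence column and no zero column exists.
The 10–90 percentile window of RobustMeanAbsoluteDeviation can be empty
for tiny VOIs; the value is then 0. These conventions guarantee a finite
107-vector for every nonempty mask — important because early, low-count
frames of a dynamic series are extracted like any other frame (the
protocol defines no frame-exclusion rule, so the package applies none).

**Aggregation.** GLCM and GLRLM build one matrix per unique 3D direction
(13 offsets) and average the features over directions (GLCM directions
without any voxel pair are skipped); GLSZM, NGTDM and GLDM use a single
merged matrix. Percentiles interpolate linearly between order statistics
(R `quantile` type 7). First-order moments use the population (1/N)
convention.

**Shape.** Mesh volume, surface area and sphericity come from a closed
triangulated iso-surface at level 0.5, computed by marching tetrahedra
with linear edge interpolation after a light Gaussian anti-aliasing of
the binary mask (sigma 0.7 voxels, applied in voxel units). The
anti-aliasing step is a deliberate numerical choice: iso-surfacing a raw
binary grid inherits the voxel staircase and overestimates surface area
by 10–25%, pushing the sphericity of a digitized ball to ~0.8–0.92,
whereas the smoothed surface reaches ~0.98 (the analytic value is 1).
The cost is a slight volume shrinkage (a few percent) and ~1% chirality
asymmetry of the fixed tetrahedral decomposition under 90° rotations —
`VoxelVolume` is exact and is the right quantity when absolute volume
matters. Masks too thin to support an iso-surface (single voxels,
1-voxel plates under smoothing) fall back to voxel-based approximations
(voxel volume, exposed-face area) and are flagged with the
`mesh_fallback` attribute. Axis lengths are `4*sqrt(eigenvalue)` of the
sample covariance of in-mask voxel-center coordinates in physical units;
maximum 2D/3D diameters are the largest pairwise distances between
surface voxels (Slice: fixed z; Column: fixed y; Row: fixed x).

## 3. Input handling

SUV normalization follows the body-weight convention
`SUV = C[kBq/mL] · weight[g] / dose[kBq]` with tissue density 1 g/mL,
which reduces to `C · weight_kg / dose_MBq`. Decay correction is assumed
already applied at reconstruction; no decay term is added. The reference
VOI is the lesion mask reflected across the grid's mid-sagittal plane
(first array axis by default, overridable), with an optional integer
translation for manual re-centering; the reflection is exact, involutive
and cardinality-preserving, and any clipping at the grid boundary is an
error rather than a silent truncation. The bundled default frame
schedule is 16×5, 7×10, 5×30, 5×60, 5×180 and 6×300 s — 44 frames,
3300 s; the loader accepts any consistent schedule and refuses
frame-count mismatches.

## 4. Classification pipeline

`nested_cv()` estimates performance with stratified outer folds
(default 5) and selects hyperparameters with an inner grid search
(default 5 folds) scored by mean inner-fold AUC, ties broken by grid
order. Every transform is fit on training rows only, including inside
each inner split: standardization (population mean/SD; zero-variance
columns — e.g. shape features after temporal MAD — map to 0 in train
and test and are flagged), then PCA truncated at the smallest component
count whose cumulative explained variance reaches 90%. Loadings follow
the sign convention that each component's largest-magnitude entry is
positive, making loading tables comparable across reruns.

The classifier is a gradient-boosted tree ensemble (xgboost,
`binary:logistic`). The tuned grid covers the three parameters that
matter most at cohort scale — `max_depth` {2, 3, 4, 6},
`min_child_weight` {1, 3, 5}, `colsample_bytree` {0.5, 0.75, 1} — with
`eta = 0.3` and 50 boosting rounds fixed (at these sample sizes the fit
saturates well before 50 rounds, and the rank-based selection metric is
insensitive to further rounds). Two non-default engine choices are deliberate: single-threaded
deterministic fitting with an explicit seed, and `tree_method = "exact"`
— on cohort-sized data the histogram approximation places split
thresholds on training values at the *edge* of a class gap instead of
its midpoint, which misclassifies held-out samples lying inside the gap.

Metrics come from pooled out-of-fold predictions (each sample scored
exactly once): AUC by the Mann–Whitney rank statistic with tie
correction, accuracy at a fixed 0.5 threshold, and precision/recall with
each class in turn as positive. Per-fold metrics are reported via
`tidy()`. For the tumor-vs-reference task both rows of a patient share a
fold (`grouping = "by_subject"`, the default in the pipeline command) to
prevent subject-level leakage; plain stratified splitting is available
since subject grouping is not part of every protocol.

A note on the reduction reported for interpretation: the per-fold PCA
used for performance and the single whole-dataset PCA used for the
loading table are different decompositions by design. Component counts
reported for interpretation come from the whole-dataset fit; performance
never does.

## 5. Attribution

`shapley_attribution()` uses exact tree-path Shapley values
(`predict(..., predcontrib = TRUE)`), aggregated as the mean absolute
value per principal component across all out-of-fold rows of all folds;
components a fold did not retain contribute zero for that fold's rows.
Additivity (contributions plus base value equal the margin prediction)
is asserted in the tests to 1e-6. `top_loadings()` maps any component to
its k highest-|loading| original features with signed loadings
(default k = 5).

## 6. The phantom generator

`generate_subject()` builds a 4D series on a 64×64×24 grid at
(3.9, 3.9, 4.2) mm spacing with the 44-frame schedule above (the
clinical 128×128×35 matrix is available by configuration; the smaller
default keeps cohort studies desk-fast and does not change any
in-VOI quantity, since extraction depends only on the lesion
neighborhood). Components:

* a spherical lesion (radius 4 voxels ≈ 250 voxels) at a jittered
  breast position, with a mirrored contralateral reference region;
* voxelwise lesion activity `TAC_region(t) × field(voxel)`, where the
  time–activity curve is the saturating form
  `K(1 − exp(−t/τ)) + b·t` evaluated at frame midpoints — a
  phenomenological uptake curve, not a compartmental model — and
  `field` is a seeded Gaussian random field smoothed to a 1.5-voxel
  correlation length with CV 0.3, shared by both classes;
* class structure: the homogeneous class ("CR") uses one τ = 300 s
  across the lesion; the heterogeneous class ("PR") is partitioned by
  seeded k-means into 6 subregions with τ drawn uniformly from
  30–1200 s, each subregion's amplitude solved so its mean over the
  last-5-frame window equals the subject's target. Static (late-window)
  intensity structure is therefore matched between classes *by
  construction* and the only systematic class difference is temporal;
* additive Gaussian noise with per-frame SD `0.3/sqrt(duration_s)` SUV,
  emulating duration-scaled counting noise (0.13 SUV on 5-s frames,
  0.017 on 300-s frames);
* subject-level dose uniform in 110–204 MBq and weight normal
  (70 ± 12 kg, truncated); volumes are stored as activity
  concentration so that `suv_normalize()` is exercised on the way back.

Default class sizes are 12 + 19, mirroring a realistic response-rate
imbalance. With `noise_scale = 0` and one subregion the construction is
an exact null: both classes generate byte-identical subjects from the
same seed.

**What the phantom does not emulate** — and hence what passing tests do
and do not show: no scanner point-spread function or reconstruction
artifacts, no attenuation/scatter residuals, no arterial input function
or plasma metabolites, no inter-frame motion, no irregular lesion
shapes, and noise that is Gaussian and spatially white rather than
reconstruction-correlated. Results on phantoms demonstrate that the
pipeline recovers a temporal-heterogeneity signal when one exists and
finds none in its absence; they do not certify clinical performance.

## 7. Problem sizes in the bundled studies

The test suite and acceptance script use: oracle equivalence on 100
random 5×5×3 quantized images against brute-force enumeration (tolerance
1e-10); a 31-subject cohort (+13 for the 88-row tumor-vs-reference
task) at the full 44-frame schedule; a permutation-null design with
n = 200; and three seeded cohorts of 60 subjects per class for the
static-vs-dynamic comparison. These sizes were chosen so that each
study's conclusion is stable under reseeding while a full run stays in
the minutes range on a single CPU.

## 8. Known limitations

* Mesh-derived shape features carry the anti-aliasing bias described
  above; absolute surface areas are ~2–8% below the digitized-surface
  value for small spheres, by design, in exchange for staircase-free
  sphericity.
* Feature extraction assumes the mask is fixed across frames; motion
  between frames must be handled upstream.
* The inner search optimizes AUC only; probability calibration at the
  0.5 threshold is not tuned (scores from small folds can cluster near
  the base rate even when ranking is perfect).
* With 107 features and cohorts of a few dozen subjects, per-fold
  standardization statistics are noisy; single subjects can project far
  from the training cloud, which is visible as occasional flat
  out-of-fold scores on miniature fixtures.
* NIfTI orientation metadata is not interpreted beyond voxel spacing;
  the mid-sagittal mirror axis is a configuration choice, not read from
  the header.
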