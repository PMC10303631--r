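# dynomics

Radiomic feature extraction extended to the time domain of dynamic PET.

Static radiomics summarizes a single 3D image of a lesion with a large
panel of quantitative descriptors. Dynamic PET acquisitions, however,
record a full 4D tracer-concentration movie, and the way a lesion's
spatial texture *evolves* over the acquisition carries information that a
single late-time image cannot: subregions with distinct kinetics rise at
different rates even when their late-time uptake looks identical.
`dynomics` operationalizes this idea for researchers working with
dynamic PET of breast lesions (or any 4D series with a binary VOI):

- a from-scratch 3D radiomic feature engine computing the canonical
  **107-feature set** — 18 first-order statistics, 14 3D shape features,
  and the five gray-level texture families (24 GLCM, 16 GLRLM, 16 GLSZM,
  5 NGTDM, 14 GLDM) — from one volume + mask, with Rcpp kernels for the
  texture-matrix accumulation and iso-surface meshing;
- **per-frame extraction** over a 4D series and robust temporal
  summarization: for every feature *f* with per-frame values
  *f₁ … f_T*,

  median(f) and MAD(f) = median(|f_t − median(f)|)

  are concatenated into an (n × 2m) design matrix;
- a **nested stratified cross-validation** pipeline — per-fold
  standardization → PCA truncated at 90% cumulative explained variance →
  gradient-boosted trees (xgboost) with an inner-loop grid search over
  tree depth, minimum child weight and column subsampling — scored by
  pooled out-of-fold AUC, accuracy, and per-class precision/recall;
- **Shapley-value attribution** of the principal components (exact
  TreeSHAP) and mapping of the top component back to its highest-loading
  original features;
- a seeded **synthetic 4D phantom generator** whose two response classes
  differ only in spatial-temporal heterogeneity, so every claim above is
  testable without access to a clinical cohort.

## Worked example

Simulate a small labeled cohort, extract static and dynamic features of
every lesion, and compare static radiomics against median+MAD dynomics
for response classification:

```r
library(dynomics)

pc    <- phantom_config(n_cr = 10, n_pr = 10, seed = 7)
feats <- cohort_features(pc, vois = "lesion")

d_static <- design_from_features(feats, "cr-vs-pr", "static")
d_mm     <- design_from_features(feats, "cr-vs-pr", "median+mad")
dim(d_static)  # 20 x 109  (sample_id, label + 107 features)
dim(d_mm)      # 20 x 216  (sample_id, label + 2 x 107 features)

cfg <- cv_config(seed = 3, grid = list(max_tree_depth = c(2, 3),
                                       min_child_weight = c(1, 3),
                                       column_subsample_ratio = c(0.75, 1)))
glance(nested_cv(d_static, cfg))$auc
#> [1] 0.51
glance(nested_cv(d_mm, cfg))$auc
#> [1] 1
```

The two classes are constructed with *matched static structure* (their
late-window mean uptake distributions are identical by design), so
static features sit at chance (AUC 0.51) while the temporal
median/MAD summaries recover the heterogeneity signal perfectly on this
small cohort (AUC 1.0). `tidy()` on a fitted `nested_cv()` gives per-fold metrics
and chosen hyperparameters, `autoplot()` draws the pooled ROC curve, and

```r
cv  <- nested_cv(d_mm, cfg)
rep <- explain_components(cv, d_mm, k = 5)
rep$components    # mean |Shapley value| per principal component
rep$top_features  # 5 highest-|loading| original features of the top one
```

maps the classifier's dominant principal component back to named
radiomic features with signed loadings.

Individual building blocks are exported too: `read_dynamic_series()`,
`suv_normalize()`, `make_static_image()`, `mirror_reference_mask()`,
`extract_features()`, `extract_per_frame()`, `temporal_median()`,
`temporal_mad()`, `standardize_fit_apply()`, `pca_reduce()`,
`compute_metrics()`, and the `run_simulate()` / `run_extract()` /
`run_classify()` / `run_explain()` pipeline commands (also available as
the `inst/cli/dynomics` Rscript).

## Documentation

The methods vignette (`vignettes/dynomics-methods.Rmd`) describes the
feature definitions and their degenerate-case conventions, the temporal
summarization model, the cross-validation design, and what the phantom
generator does and does not emulate.
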