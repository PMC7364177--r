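# mvpakit

Cross-validated multivariate pattern analysis (MVPA) of volumetric
neuroimaging data, as a scriptable R package.

Univariate analyses ask whether single voxels differ between conditions;
MVPA asks whether the *joint pattern* across many voxels can predict, for
held-out subjects, a class label (patient vs. control) or a continuous
score (e.g. reaction time). mvpakit is for researchers who want that
analysis reproducible and scriptable end to end: voxel matrices extracted
through a NIfTI mask, leakage-safe preprocessing, seven standard
estimators behind one contract, searchlight information mapping,
permutation inference with family-wise-error correction, and multimodal
data fusion — all driven either from R or from a single saved
configuration file.

## The statistics at its core

For a two-class decoding analysis with confusion counts TP, TN, FP, FN
pooled over cross-validation folds:

    Accuracy    = (TP + TN) / (TP + FN + TN + FP)
    Sensitivity = TP / (TP + FN)
    Specificity = TN / (TN + FP)

together with the ROC curve/AUC over pooled decision values and, for
linear models, per-fold weight vectors mapped back into voxel space. For
regression, performance is the prediction precision r = cor(predicted,
true) over pooled out-of-fold predictions.

Significance is non-parametric: the labels are shuffled N times, the
entire pipeline (including any training-fold feature selection) re-runs
per shuffle, and

    p = #{null statistics >= observed} / N,

reported as the bound P < 1/N when the count is zero. For searchlight
maps, the per-permutation *maximum* statistic across all sphere centers
forms a common null distribution; comparing each center against it yields
FWE-corrected p-values.

Preprocessing (Z = (x − m)/σ with training-set m, σ; PCA keeping the top
components that explain ≥ 95% variance; F-score / weight / LASSO feature
selection) is always fitted on training folds only. The decision-level
fusion rule sums sign-coherent, confidence-weighted decision values across
per-modality classifiers; feature-level fusion concatenates blocks.

## A worked example

Everything below runs on synthetic volumes — the package generates its own
NIfTI fixture sets, so there is nothing to download.

```r
library(mvpakit)

# 20 "patients" + 20 "controls": 8x8x8 volumes, spherical mask,
# a 1-SD mean shift inside a 3x3x3 signal box, 5 stratified folds
fix <- make_classification_volumes(fixture_spec(effect = 1, seed = 7))

cv <- run_cv(fix$data, fix$labels, fix$folds,
             model = make_model("svm"),            # C-SVC, linear, c = 1
             preprocess = list(step_zscore()))
cv
#> <mvpa_cv> classify, 5 folds, 40 samples
#>   accuracy 0.925 | sensitivity 0.950 | specificity 0.900 | AUC 0.982
```

92.5% of the 40 held-out predictions are correct; 95% of the patients
(class +1) and 90% of the controls are recognized. `tidy(cv)` gives the
per-fold confusion counts, `glance(cv)` the pooled metrics,
`autoplot(cv)` the ROC curve, and `cv$weights$mean` the mean voxel weight
map (`write_map(cv$weights$mean, fix$space, "weights.nii")` puts it back
into brain space).

```r
pt <- permutation_test(fix$data, fix$labels, fix$folds,
                       preprocess = list(step_zscore()),
                       n_perm = 199, seed = 8)
pt
#> <mvpa_permutation> observed accuracy = 0.9250 over 199 permutations: P < 0.00502513 (i.e. P < 1/199)
```

No label shuffle reaches the observed accuracy, so the p-value is reported
as the bound P < 1/199 — never as zero.

```r
sl <- run_searchlight(fix$data, fix$labels, fix$folds, radius = 2)
sl
#> <mvpa_searchlight> radius 2, 160 centers; statistic (accuracy): mean 0.707, max 1.000
```

Centers whose 33-voxel sphere overlaps the signal box decode perfectly;
distal centers hover at chance. `autoplot(sl)` shows the accuracy map
slice by slice; `permutation_test_searchlight()` adds uncorrected and
FWE-corrected p-maps.

The same analysis as a saved, re-runnable configuration:

```r
fix <- make_classification_volumes(fixture_spec(effect = 1, seed = 7), dir = "fixtures")
cfg <- resolve_config(list(
  input = list(samples = fix$paths$samples, mask = fix$paths$mask,
               labels = fix$paths$labels, folds = fix$paths$folds),
  preprocess = list(list(step = "zscore")),
  model = list(algorithm = "svm"),
  output = list(dir = "results")
))
run_config(cfg)          # metrics.csv, ROC, weight maps, resolved_config.yaml, log
```

or from a shell via the thin CLI: `Rscript inst/cli/mvpa.R run cfg.yaml`.

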