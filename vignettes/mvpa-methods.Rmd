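---
title: "Decoding models, permutation inference, and design choices in mvpakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding models, permutation inference, and design choices in mvpakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mvpakit performs multivariate pattern analysis (MVPA) of volumetric
neuroimaging data: instead of testing each voxel separately, a decoding
model reads the joint pattern across many voxels to predict a class label
(e.g. patient vs. control) or a continuous score (e.g. reaction time) for
held-out subjects. This vignette explains the statistical machinery, the
defaults and their units, what the synthetic fixtures do and do not
emulate, and the design decisions taken where more than one reasonable
convention exists.

## The decoding model and its cross-validation contract

The data model is a samples-by-features matrix. For volumetric input each
row is one subject's 3-D map (ReHo, fALFF, GMV, ... — computed upstream)
restricted to a binary mask; each column is one in-mask voxel. Column
order is canonical: ascending linear voxel index with the x axis varying
fastest. This order is a pure function of the mask, never of the data, so
weight maps written back to NIfTI are reproducible across runs and
machines. Tabular (CSV) input is supported for non-image features
(connectivity, behavior, genetics); it simply has no geometry, so maps and
searchlights are unavailable for it.

Performance is always estimated by K-fold cross-validation: every fold
serves once as the test set while the remaining folds train the model.
The engine enforces the leakage contract structurally: *every* fitted
quantity — Z-scoring means and SDs, PCA loadings, F scores, LASSO
coefficients, the classifier itself — is computed from the training folds
only and then applied, frozen, to the held-out fold. The test suite
asserts this by perturbing held-out samples and checking bit-identical
fitted state. When the package assigns folds itself, the split is
stratified: per-class counts per fold differ by at most one.

Classification performance is reported as accuracy, sensitivity and
specificity from the confusion counts pooled over folds (class +1 is the
"positive" class). Pooling is a deliberate choice: with uneven folds the
unweighted mean of per-fold accuracies differs from the pooled estimate,
so both are reported (`accuracy` and `accuracy_fold_mean`) and the
per-fold table is always available via `tidy()`. The ROC curve and AUC are
computed once from the pooled out-of-fold decision values, not per fold.
Regression performance ("prediction precision") is the Pearson correlation
between pooled out-of-fold predictions and the true scores — with
leave-one-out folds this is the only definable version, since a
single-sample fold has no within-fold correlation.

## Estimators, defaults, and the unified decision value

Seven estimators are exposed under one contract; four of them (SVM, KNN,
decision tree, random forest) also support regression. Optimization
internals are delegated to the standard backends (libsvm via e1071, rpart,
randomForest, glm); the package owns defaults, seeding and weight
extraction. Defaults follow the field's conventions: C-SVC with a linear
kernel and cost `c = 1` (epsilon-SVR with `p = 0.1` for regression; further
SVM parameters `g = 0.1`, `d = 3`, `r = 0`, `nu = 0.5`), `k = 11` nearest
neighbors, 500 forest trees. KNN and a two-class LDA are implemented
directly because their tie-breaking and singularity behavior are part of
the documented contract: the k-th-neighbor distance tie includes the
lower-index training sample; a singular pooled covariance gets a ridge of
`1e-6 * trace/p` once, with a warning, before LDA gives up and suggests
dimension reduction.

Classifiers disagree about what their raw output means, so decision-level
fusion needs a common scale. The package maps every classifier to a
sign-coherent decision value: the signed margin for SVM, `2 * (P(+1) -
0.5)` for logistic regression, naive Bayes, tree and forest, the signed
discriminant for LDA, and the signed vote fraction `(votes+ - votes-) / k`
for KNN. The predicted class is the sign; an exact tie (decision value 0,
possible with even `k` or probability exactly 0.5) deterministically
predicts +1. For the three affine models (linear SVM, logistic, LDA),
`linear_weights()` returns the `(w, b)` of the underlying discriminant —
for the SVM this *is* the decision value; for logistic/LDA it is the
log-odds/discriminant whose sign agrees with the bounded decision value.
Per-fold weight vectors are projected back through the preprocessing chain
(selection scatter, PCA loadings, Z-scale division) into voxel space, so
the mean weight map lives in the original geometry. Row-direction
Z-scoring is a per-sample transform with one-to-one column correspondence;
weights pass through it unchanged.

The naive Bayes likelihood is Gaussian per feature — appropriate for
continuous voxel data; a discrete-likelihood variant is not provided.

## Feature preprocessing

*Z-scoring* uses `Z = (x - m) / sigma` with the population (divide-by-n)
standard deviation; the convention is documented because sample-SD
implementations also exist and neither is canonical. Constant training
columns (`sigma = 0`) map to 0 rather than NaN so they stay inert.
Column direction fits `m` and `sigma` on training data; row direction
normalizes each sample by its own statistics and therefore involves no
training-set state at all.

*PCA* keeps the smallest number of components whose cumulative explained
variance reaches the threshold (default 0.95; i.e. the top n explain at
least 95% while the top n-1 do not), capped at `min(n_train - 1,
n_features)`. An explicit component count may exceed neither cap.

*Feature selection* ranks features by univariate F score or by the
absolute weight of a linear model, keeping a count or fraction (floor,
minimum 1; ties broken toward the lower index, and infinite F scores —
distinct class means with zero within-class variance — sort first). For
continuous labels the F score is the univariate regression F,
`(n-2) r^2 / (1 - r^2)`, the natural analogue of the two-class ANOVA F.
The LASSO route minimizes `(1/2N) sum (y_i - w0 - x_i'w)^2 +
lambda sum |w_j|` with `lambda` chosen on a 100-value log grid spanning
`lambda_max` down to `lambda_max * 1e-4` by 10-fold cross-validation
*inside the training fold* (deterministic, stratified folds), keeping the
features with nonzero coefficients; an empty selection is an error, never
a silent fallback. A configuration may list a *series* of selection
amounts; each runs as an independent analysis and the joint report
annotates the Bonferroni-adjusted alpha `0.05/m` — reporting only the best
amount would be circular.

## Searchlight mapping

The searchlight assigns each in-mask voxel the cross-validated statistic
obtained from the sphere centered on it. A sphere of radius r (in voxel
units) is the closed ball of lattice offsets with squared norm at most
r^2 — radius 1 gives the center plus its 6 face neighbors (7 voxels),
radius 2 gives 33. Including the boundary (closed ball) is a convention;
the tests pin it against exhaustive lattice enumeration. Radius in
millimeters is available as an option and scales each axis by the voxel
size; the voxel-unit default ignores anisotropy. Spheres are clipped at
the volume and mask boundary; spheres with fewer than 2 voxels still run,
and the sphere-size map lets users filter them afterwards. Per-center
randomness derives from `(seed, center index)`, so maps are bit-identical
regardless of execution order or worker count.

## Permutation inference and FWE correction

Significance of a decoding statistic is assessed non-parametrically: the
label (or score) vector is shuffled N times, the *entire* pipeline —
including any training-fold feature selection or PCA — is re-run with the
fold structure held fixed, and the p-value is the fraction of null
statistics greater than or equal to the observed one. Re-running the
selection inside every permutation is the expensive but honest choice: a
null built on features selected once from the true labels would be
optimistic. The estimator is `count/N` (not `(count+1)/(N+1)`); when the
count is zero the report states the bound `P < 1/N` rather than `P = 0`,
because N permutations cannot resolve smaller probabilities. Shuffling is
applied to the whole label vector once per iteration: the searchlight FWE
procedure requires the same relabeling across all centers, and a single
global shuffle applies it consistently to every fold.

For searchlight maps, multiple comparisons are handled by the
max-statistic procedure: per permutation, only the maximum statistic
across all centers is kept; each center's observed statistic is then
compared against this common null distribution of maxima. This controls
the family-wise error rate and is by construction never more liberal than
the uncorrected per-center p-value. Cluster-extent thresholds are left to
reporting (the statistic and p maps are written as NIfTI volumes).

## Data fusion

Two strategies combine feature types. *Concatenation* stacks the blocks'
columns into one matrix before a single cross-validated analysis; because
different measures can live on very different scales, each block can be
column-z-scored first (off by default — measures like fALFF and FC already
share the [-1, 1] range, and silent renormalization would change results
invisibly). The fused space is tabular, but a block-to-column index is
retained so fused weight vectors can be reported per block. *Voting* fits
one model per block on identical folds and sums the per-sample decision
values: each model's vote is signed by its decision and weighted by its
own confidence, which is exactly what the unified decision-value scale
was built for. The fused class is the sign of the sum (tie to +1);
regression fusion is the unweighted mean of predictions, since an SVR's
decision value *is* its prediction and offers no separate confidence.
Both strategies reduce exactly to the plain pipeline for a single block.

## Synthetic fixtures: what they emulate and what they do not

All tests and the acceptance script run on synthetic volume sets so no
data download is required. The generator draws i.i.d. Gaussian voxel noise
(`noise_sd`, default 1) on an 8x8x8 grid and adds a mean shift of
`effect * noise_sd` (classification) or a slope times the subject's score
(regression) inside a 3x3x3 signal box. The default mask is the inscribed
sphere (radius 3.5 voxels, 160 voxels) — brain masks are round-ish inside
rectangular grids, and this exercises the searchlight's boundary clipping;
a full-grid mask is available. Default sample sizes are 20 per class
(matching a small patient-control study) with 5 stratified folds;
regression scores are Uniform(0.3, 0.9) seconds, reaction-time-like, with
slope 1. Identical spec and seed give byte-identical files.

These fixtures deliberately do *not* emulate real fMRI: no spatial
autocorrelation (an optional smoothing flag exists but is off), no
physiological or motion artifacts, no hemodynamics, no class-dependent
covariance. Passing tests therefore demonstrate the *statistical
machinery* — calibration, leakage-safety, geometry — not that any
particular real dataset is decodable.

## Problem sizes used by the test suite

The statistical checks run at desk scale, chosen once: the type-I-error
calibration uses 200 null datasets (effect 0, n = 40, 8x8x8 grid, 160-voxel
spherical mask, 5 folds) with N = 99 permutations each at alpha = 0.05,
judged against the exact binomial 99% acceptance interval; the reduced
super-uniformity check uses 60 datasets of n = 16 with N = 19; the fusion
gain and selection-trend simulations average 50 and 20 seeds respectively.
The acceptance script reports the mean of a 500-permutation null
distribution of cross-validated linear-SVM accuracy on a signal-free
n = 40 volume set, in percent — for balanced classes it should sit at the
50% chance level.

## Known limitations

Only two-class classification is supported (by design); multi-class,
surface (GIFTI) data, 4-D multi-sample containers, spreadsheet input,
nested hyperparameter search beyond the LASSO lambda rule, stacking or
multiple-kernel fusion, and cluster-level inference are out of scope.
Exact voxel-order agreement with other MVPA tools is not checkable, since
the field has no canonical in-mask ordering; within this package the
ordering is fixed and documented. Undefined metrics (sensitivity with no
positive test samples; correlation of a constant prediction) are reported
as missing, never coerced to 0.
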