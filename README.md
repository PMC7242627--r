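# boldnine

Case–control classification of resting-state fMRI from nine voxel-wise
temporal summary measures, with a small 3D convolutional network and a
linear-SVM baseline.

## The problem

A resting-state BOLD run is a 4D array — tens of thousands of voxels, each
a time series — while clinical cohorts number in the hundreds to low
thousands of subjects, spread over acquisition sites with their own scanner
signatures. `boldnine` implements a framework for this regime: collapse
each run's temporal dimension into nine 3D **summary measures**, each one
number per voxel —

| measure | what it summarizes |
|---|---|
| ReHo | Kendall's W, \(W = 12S/(K^2(n^3-n))\), of a voxel with its spatial neighbors |
| ALFF | one-sided spectral amplitude summed over 0.01–0.1 Hz |
| fALFF | the same band as a fraction of total amplitude |
| DC | weighted degree centrality: sum of supra-threshold correlations (r > 0.25) |
| EC | weighted eigenvector centrality: Perron vector of (1 + r)/2 |
| LFCD | seed-correlation weight of the spatially connected supra-threshold cluster |
| entropy | Shannon entropy of the voxel's 32-bin value histogram |
| VMHC | correlation of a voxel with its left–right mirror |
| autocorr | lag-1 autocorrelation of the voxel series |

— then classify subjects (patient = 1, control = 0) from these volumes
under three strategies: one model per measure (`sm:<measure>`), a
majority-vote ensemble of the nine per-measure models (`mm_ensemble`), or
one model on all nine measures at once (`mm_model`; nine channels for the
CNN, concatenated features for the SVM).

The CNN is deliberately small — avgpool(2) → conv(64, 3³, ELU) →
conv(16, 3³, ELU) → maxpool(2) → dense(16, ELU) → dense(1, sigmoid), valid
convolutions, **257,585 trainable parameters** on the single-channel
45×54×45 (4 mm MNI) grid — and trains with SGD (lr 0.001, momentum 0.9),
binary cross-entropy, batches of 32, no regularization, keeping the
best-validation-accuracy epoch. Evaluation uses five-fold CV with a fixed
stratified 10% test set shared by all folds, or leave-site-out CV; metrics
are balanced accuracy and F1. Occlusion analysis zeroes one atlas region
at a time in the normalized test inputs and ranks regions by the resulting
performance drop. A seeded multi-site synthetic BOLD generator makes every
stage testable without any imaging download.

## Worked example

Simulate a 60-subject, three-site cohort whose patients carry elevated
local synchrony in one region, compute ReHo and ALFF maps, and evaluate a
single-measure SVM under five-fold CV:

```r
library(boldnine)

grid <- c(12, 12, 12)
roi <- array(FALSE, grid); roi[4:8, 4:8, 4:8] <- TRUE
spec <- cohort_spec(n_subjects = 60, grid_shape = grid,
                    n_timepoints = 120, seed = 7)
coh <- generate_cohort(spec, list(effect_spec("local_synchrony", roi,
                                              magnitude = 0.6)))
maps <- summarize_runs(coh$runs, measures = c("reho", "alff"))
splits <- split_fivefold(coh$manifest, test_fraction = 0.15, k = 5, seed = 7)
res <- run_strategy(maps, coh$manifest, splits, "sm:reho", "svm")
res
#> <eval_result> sm:reho | svm | fivefold CV (5 folds)
#>   mean balanced accuracy 1.000 | mean F1 1.000

quantile(permutation_null(res, n_perm = 100, seed = 7), 0.95)
#> 95th percentile of the permutation null: 0.6
```

The SVM separates the groups perfectly on the 8-subject common test set
(balanced accuracy 1.000 in every fold), far above the 0.6 that chance
alignment of these predictions with shuffled labels reaches at the 95th
percentile — the synchrony effect is strong at magnitude 0.6 and ReHo is
exactly the measure built to see it. Swapping `"sm:reho"` for `"sm:alff"`
drops performance to the chance band, since the variance-preserving
synchrony effect leaves amplitude spectra alone.

`glance()`/`tidy()` return the fold-mean and per-fold metrics as tibbles,
`autoplot()` draws them; `run_strategy(..., keep_fits = TRUE)` followed by
`run_occlusion(fit, atlas)` attributes the performance to atlas regions.
`inst/cli/boldnine.R` wraps the same functions as
`simulate | summarize | evaluate | occlude | agreement` subcommands.

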