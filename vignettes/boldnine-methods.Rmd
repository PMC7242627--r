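---
title: "Classifying resting-state fMRI with voxel-wise summary measures and a small 3D-CNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying resting-state fMRI with voxel-wise summary measures and a small 3D-CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resting-state fMRI yields a 4D BOLD series per subject: tens of thousands of
voxels, each sampled over a hundred or more timepoints. Case-control
classification from such data faces two structural obstacles: the temporal
dimension makes the input enormous relative to any clinical cohort, and
multi-site aggregation injects scanner- and protocol-dependent shifts that
dwarf diagnostic effects. `boldnine` implements a classification framework
built around a drastic, hypothesis-driven dimensionality reduction: each 4D
run is collapsed to nine 3D *summary measures*, one number per voxel per
measure, each capturing a distinct statistical facet of the local time
series. Subjects (patient versus control) are then classified from these
volumes with a deliberately small 3D convolutional network and a linear-SVM
baseline.

## The nine summary measures

For an in-mask voxel with series $x_1, \dots, x_n$ sampled every `TR`
seconds:

* **ReHo** — Kendall's coefficient of concordance
  $W = 12 S / (K^2 (n^3 - n))$ across the voxel and its spatial neighbors
  (default 27-voxel cube; 7 and 19 supported), with
  $S = \sum_i (R_i - \bar R)^2$ over rank sums $R_i$. Ties receive
  mid-ranks and no tie correction is applied; rank invariance makes ReHo
  insensitive to monotone signal transforms.
* **ALFF** — the sum of one-sided amplitude-spectrum values
  ($|X_k|/\sqrt{n}$, DC excluded) over 0.01–0.1 Hz.
* **fALFF** — the same band sum divided by the total over all positive
  frequencies, a scale-free quantity in $[0,1]$.
* **Degree centrality (weighted)** — the sum of Pearson correlations with
  every other in-mask voxel exceeding a threshold $r_{thr}$ (default 0.25,
  positive edges only). Computed in voxel blocks; block size never changes
  the result.
* **Eigenvector centrality (weighted)** — the Perron eigenvector of the
  similarity matrix $A = (1+r)/2$, computed matrix-free by power iteration
  (tolerance $10^{-6}$, uniform start), unit Euclidean norm, nonnegative
  orientation. The $(1+r)/2$ transform guarantees a nonnegative matrix so
  the leading eigenvector is well defined.
* **LFCD (weighted)** — seed-wise breadth-first growth over spatially
  connected neighbors (26-connectivity by default), admitting a voxel when
  its correlation *with the seed* exceeds $r_{thr}$; the map value is the
  sum of seed correlations over the admitted cluster. Spatially
  disconnected voxels never contribute, however correlated.
* **Entropy** — Shannon entropy (natural log) of the histogram of the
  voxel's own values over 32 equal-width bins spanning its range.
* **VMHC** — the correlation between each voxel and its left–right mirror
  across the first spatial axis; voxels whose mirror leaves the mask get 0.
* **Autocorrelation** — the lag-1 Pearson autocorrelation by default; a
  `decorrelation_lag` mode returns the smallest lag at which the
  autocorrelation falls below $1/e$, since "autocorrelation lag" admits
  either reading. Neither mode is privileged; the default is the simpler
  one.

Degenerate inputs follow one convention everywhere: a constant series has
no defined rank ordering, correlation, or spectrum shape, and contributes
the contract value 0 rather than NaN.

Several of these conventions are genuinely open choices — the ReHo
neighborhood, the histogram entropy estimator, the correlation threshold,
whether connectivity graphs are thresholded at all — and are therefore
parameters of `measure_params()` rather than hard-coded facts, with the
defaults above.

## Feature preparation

Per measure, a *feature scaler* (`fit_scaler()`/`apply_scaler()`) computes
the voxel-wise mean and population standard deviation over **training
subjects only** and z-scores every subject against those statistics. The
scaler is refitted inside every cross-validation fold: refitting per fold
is the only reading that cannot leak test information, and the test suite
verifies that perturbing held-out subjects leaves all fitted artifacts
unchanged.

The CNN consumes the scaled volumes directly (out-of-brain voxels are ~0
after scaling). The SVM path first builds a *group mask* per measure —
voxels whose raw value is nonzero in at least 90% of the training subjects
— and flattens the masked, scaled volumes into a subjects × features
matrix (first spatial axis fastest). Masking is described only for the SVM,
so only the SVM uses it. The nine per-measure feature blocks concatenate in
one fixed canonical order (`measure_names()`), the same order used for the
nine-channel CNN input, so persisted models and matrices are reproducible.

## The classifier

The 3D-CNN is intentionally small: average-pool (2, stride 2) →
convolution, 64 filters of size 3 (valid, ELU) → convolution, 16 filters
of size 3 (valid, ELU) → max-pool 2 → flatten → dense 16 (ELU) → dense 1
(sigmoid). Valid (unpadded) convolutions with floor-division pooling are
the only configuration that reproduces the reference parameter count —
257,585 trainable parameters on the single-channel 45×54×45 grid — which
is also what pins that input grid. Training uses binary cross-entropy, SGD
with learning rate 0.001 and momentum 0.9, mini-batches of 32 (the last
incomplete batch is used), at most 50 epochs, and **no regularization** of
any kind. After each epoch the validation accuracy is recorded; the weight
snapshot with the best validation accuracy is kept, ties resolving to the
earliest epoch. Weight initialization is fan-in-scaled uniform under a
fixed seed — the initialization scheme, tie handling, and the use of plain
(not balanced) validation accuracy are artifact choices, as no convention
is canonical here.

The absence of regularization is itself informative: trained well past
validation convergence, the network drives training accuracy to ~100%
while validation accuracy lags — the classic overfitting signature, which
the acceptance suite reproduces on a synthetic cohort.

Two engines implement the identical arithmetic: a pure-R reference
(BLAS-backed shift-and-GEMM convolutions) and compiled RcppArmadillo
kernels, the default. The test suite holds them to numerical agreement on
forward scores, training logs and final weights, and checks the analytic
gradients against numerical differentiation.

The baseline is a linear soft-margin SVM with cost 1 (the common toolkit
default), fitted on training rows only, with signed margins oriented so
positive means patient.

## Strategies and cross-validation

Three strategies (`run_strategy()`): `sm:<measure>` trains one classifier
per single measure; `mm_model` feeds all nine measures to one classifier
(stacked channels for the CNN, concatenated features for the SVM);
`mm_ensemble` trains nine single-measure classifiers and takes the
majority vote of their binary predictions — nine voters, so ties are
impossible, and an even voter count is rejected outright.

Two schemes: *five-fold CV* first carves out a fixed 10% test set —
stratified by site × label so that the common benchmark is usable for
per-site reporting; the stratification detail is our choice, as only
"random" is specified upstream — shared identically by all folds, then
rotates the remaining 90% through validation. *Leave-site-out CV* holds
each site out entirely as the test set and splits the rest 90/10 into
training and validation. Reported metrics are balanced accuracy
(mean of sensitivity and specificity, patient = positive class by clinical
convention) and F1, averaged across folds — per-fold averaging matching
the "averaged over folds" description; whether pooled-test computation was
meant instead is unknowable, and the choice is documented rather than
silent.

Agreement between models is measured with Kendall's tau-b between binary
test-set predictions, per fold, then averaged; tau-b's tie correction is
required because binary vectors are almost entirely ties. Fold-pairs where
a model predicts a single class are undefined and are excluded with a
warning.

A permutation null (`permutation_null()`) re-pairs each fold's fixed
predictions with shuffled labels, giving the chance distribution of the
mean metric without retraining.

## Occlusion attribution

`run_occlusion()` zeroes one atlas region at a time in the already
normalized test inputs — zero is the neutral value in scaled space, which
is why occlusion follows normalization by default (occluding raw inputs
is exposed as the alternative; the original ordering is not stated) — and
re-scores the stored per-fold models without retraining. For the SVM the
corresponding feature columns are zeroed. The drop in fold-averaged
balanced accuracy relative to the un-occluded baseline ranks the regions;
the baseline row reproduces the evaluation's numbers bit-exactly. The
procedure is descriptive: no statistical test is attached to the drops.

## The synthetic cohort generator

`generate_cohort()` emulates exactly the structure the pipeline must
handle: multi-site cohorts of two diagnostic groups, voxel series made of
AR(1) noise (coefficient 0.3) plus shared in-band sinusoidal background
with random voxel loadings, per-site mean/scale shifts, and an ellipsoidal
brain mask. Group effects are injected per region:

* `local_synchrony` — region voxels of affected subjects share a latent
  AR(1) component carrying a `magnitude` fraction of their variance. The
  mixture is variance-preserving and spectrally matched to the noise, so
  it raises ReHo (and degree centrality) while leaving ALFF essentially
  untouched — this is what makes effect-measure specificity testable.
* `low_freq_amplitude` — an in-band sinusoid with an independent random
  phase per voxel; raises ALFF without synchronizing neighbors.
* `homotopic_coupling` — the shared-latent mixture applied to the region
  and its left–right mirror; raises VMHC.

At magnitude 0 the groups are exchangeable by construction. All randomness
derives from one seed per subject, so cohorts regenerate identically.

What the generator does **not** emulate: hemodynamic response shapes, head
motion, physiological noise spectra, spatial autocorrelation of real BOLD,
or realistic effect topographies. Passing tests therefore demonstrate that
the pipeline's machinery — measures, leakage-safe scaling, training,
voting, splitting, occlusion — behaves correctly and recovers effects of
the kind each measure is designed to detect; they say nothing about
classification accuracy attainable on real clinical data, which depends on
preprocessing and cohort properties outside this package's scope
(motion correction, nuisance regression and spatial normalization are
deliberately not implemented).

## Numerical choices and problem sizes

* Spectral amplitudes are $|X_k|/\sqrt{n}$ (square root of periodogram
  power); no detrending or windowing by default — detrending belongs to
  preprocessing, though a linear-detrend flag exists.
* fALFF, ReHo, VMHC and autocorrelation values are clamped to their
  theoretical ranges against floating-point drift.
* Power iteration failure (1000 iterations without convergence) is an
  error carrying a residual diagnostic, not a silent result.
* Dense voxel × voxel work (degree centrality) streams over blocks of
  2048 voxels; the blocked result is bit-identical to the dense one.
* Tests run on grids of 4³–24³ with 30–120 timepoints; the overfitting
  check trains 70 epochs on 76 subjects at 24³, the effect-recovery check
  uses five seeded 80-subject cohorts at 12³, and the occlusion check five
  seeded 48-subject cohorts at 12³. `scripts/acceptance.R` runs the
  overfitting experiment at its full stated scale (200 subjects, 24³, 60
  epochs). These sizes are the package's chosen desk-scale study
  conditions; the architecture accepts the full 45×54×45 grid unchanged.

## Known limitations

* The CNN trains on CPU; full-size (45×54×45) cohorts train at minutes per
  epoch, which is practical for sanity runs, not for hyperparameter
  sweeps (and none are offered — the architecture is fixed by design).
* Site harmonization (location/scale adjustment per site) is out of scope;
  the feature scaler mitigates but does not remove site effects, and the
  test suite verifies only that site shifts alone do not masquerade as
  diagnostic signal under stratified splits.
* Surface-based variants, frequency sub-bands, and sample/approximate
  entropy families are not implemented.
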