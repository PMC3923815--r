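---
title: "Multimodal fusion of PET features and neuropsychological scores: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fusion of PET features and neuropsychological scores: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofuse)
```

## The problem

Subjects with mild cognitive impairment (MCI) split, over a few years of
follow-up, into a *stable* group and a group that *converts* to Alzheimer's
disease. neurofuse implements a computer-aided diagnosis pipeline that
predicts conversion from two heterogeneous sources acquired at baseline:

* an FDG-PET brain volume, reduced to a handful of image features, and
* a panel of five neuropsychological scores (immediate recall, cued recall,
  intrusions, phonemic fluency, semantic fluency), optionally extended with
  the MMSE score and age.

The two sources live on incommensurate scales and have wildly different
dimensionality (thousands of voxels against five to seven scores), so the
pipeline is organized around two questions: how to compress the image into
few features, and at which stage to fuse the sources.

## Preprocessing

Volumes are assumed spatially co-registered; neurofuse performs no
registration (this is logged as an assumption when volumes are loaded
without normalization). Intensities are normalized by the mean over a
reference-region mask — the cerebellum in the intended application, a
region relatively spared by the disease — which removes per-subject
global-uptake variability. The mean (rather than the median or another
summary) is used: it is linear, conventional in the reference-region
normalization literature, and makes the operation idempotent and exactly
scale invariant. Masked brain voxels are then flattened into a
subjects-by-voxels matrix in a fixed lexicographic voxel order (first axis
slowest) so that fitted loadings are reproducible.

## Dimensionality reduction

Three backends produce per-subject image features; all fit strictly on the
training subjects of the current cross-validation fold.

**PCA.** Rows are normalized to unit norm and the mean image is
subtracted. Because voxels far outnumber subjects, the eigendecomposition
of the voxel-space covariance is obtained from the N-by-N Gram matrix of
the centered rows ("eigenface" trick); eigenvectors are mapped back to
voxel space and unit-normalized. Component importance is the eigenvalue.
The sign of an eigenvector is free; neurofuse forces the largest-magnitude
loading positive so runs are deterministic.

**PLS.** NIPALS partial least squares against the class labels coded
−1/+1 and mean-centered, on the column-centered image matrix. Each round
extracts the direction of maximal covariance with the (deflated) label
block and deflates X by the rank-one score/loading product, so that on
training data X = T·Pᵀ + E with E orthogonal to the scores. New subjects
are projected with R = W(PᵀW)⁻¹. At most min(N−1, 20) components are
extracted, stopping early when the residual is numerically exhausted.

**ICA.** Data are centered and whitened to k dimensions by Gram-trick PCA
(k defaults to min(N−1, 20); the backend never states how many components
to keep before selection, so the cap is a package choice), then a square
unmixing matrix is estimated by the symmetric fixed-point iteration with
the tanh contrast, which maximizes the nongaussianity of the recovered
sources. The per-subject features are the unmixed source activations (not
projections onto mixing columns). The iteration is seeded and
deterministic; if it has not converged after `maxit` sweeps (default 2000,
tolerance 1e-6 on the change of unmixing directions) an error is raised
rather than returning a partial result.

**Component selection.** PCA components are selected by cumulative
variance with a default threshold of 75%; PLS and ICA components by the
cumulative Fisher discriminant ratio (FDR) of their training scores with a
default of 85%. The FDR of a feature is (μ₁−μ₂)²/(σ₁²+σ₂²) with unbiased
(n−1) class variances — the estimator is a package choice, since the
ratio is usually written without specifying one. Components are ranked by
descending importance (ties keep original order, for determinism) and the
smallest prefix reaching the threshold is kept. Both thresholds are
exposed as configuration. A perfectly separating component (infinite FDR)
is selected alone.

## Fusion strategies

A support vector machine with accessible decision values is the base
classifier; the quadratic-programming solver is kernlab's, while the
fusion logic is neurofuse's. Both feature blocks are z-scored with
training-fold statistics before anything else — the sources' raw scales
are incommensurate and the backends give no scaling rule, so per-feature
standardization is the package's convention.

* **Early integration** concatenates the standardized score panel and the
  selected image features into one vector per subject and trains a single
  SVM.
* **Intermediate integration** (multikernel classification) builds one
  kernel per source and trains the SVM on the weighted sum
  βK_image + (1−β)K_psych, β on a grid over [0, 1] selected by inner
  cross-validation. A convex combination of positive semidefinite kernels
  is positive semidefinite, so the combined matrix is a valid kernel.
* **Late integration** trains one SVM per source and, at prediction time,
  keeps the class whose decision value lies farther from its separating
  hyperplane (the absolute functional margin as confidence; the
  comparison deliberately uses |d|, the "confidence" reading). On an
  exact tie, the source with the higher individual inner-CV accuracy
  wins; if those accuracies are unavailable or equal, the psychometric
  source is the deterministic fallback.

Decision values are signed functional margins, not geometrically
normalized distances; both sources pass through identical standardization,
so their margins are compared on the same scale. Positive decisions mean
"converter".

**Hyperparameters.** Cost C from the symmetric powers-of-two grid
2⁻⁵…2⁵; kernels linear and RBF (bandwidth grid 2⁻³…2³ over standardized
features); intermediate weights β ∈ {0, 0.1, …, 1}. Selection is
leave-one-out within the training fold, maximizing accuracy, with ties
broken toward the linear kernel and the smaller cost. The inner loop
reuses the outer fold's standardization and reduction basis and re-fits
only the classifier (and weights): the outer held-out subject contributes
to no statistic, which is the leakage that matters; re-fitting the
reduction inside the inner loop as well would multiply cost without
changing what the outer estimate measures. When a single hyperparameter
candidate is configured the inner loop is skipped.

## Evaluation

Leave-one-out cross-validation refits preprocessing statistics, reduction,
selection, scalers and classifier on the N−1 remaining subjects for every
fold. Reference normalization is per-subject (no cross-subject statistic),
so it is applied once up front. The positive class is "converter", so
sensitivity counts detected converters. Likelihood ratios are
LR+ = sens/(1−spec) and LR− = (1−sens)/spec, with an Inf sentinel (logged,
not raised) at degenerate specificities. Reported rates are rounded half
away from zero to two decimals only at display time.

ROC curves sweep the threshold over the pooled leave-one-out decision
values (pooling across folds is a package convention); tied decisions
cross the threshold simultaneously, and the trapezoidal AUC then equals
the probability that a random converter outranks a random stable subject
with ties counted one half.

The permutation test replaces every subject's score panel with
independent uniforms over the observed per-score [min, max], reruns the
complete leave-one-out pipeline, and counts the permuted accuracies
strictly greater than the observed one: p = (#{permuted > observed})/n.
Ties do not increment the count (an add-one-smoothing flag is deliberately
absent: the strict count is the documented convention). The reference
replication is 1000; because each draw is a full nested LOO, reduced
replication (e.g. 100) is supported and used in the test suite.

## The synthetic cohort generator

The clinical database the pipeline was designed around is not publicly
deposited, so the generator is a first-class, tested module that emulates
its statistical structure:

* Group sizes default to 20 stable / 26 converter, the reference cohort
  shape.
* MMSE (27.10 ± 1.62 vs 25.26 ± 2.76), age (65.55 ± 7.76 vs 72.42 ± 5.91)
  and the optional education column use the published demographic values.
  The five cognitive scores have no published distributions, so their
  defaults are clinically plausible values for stable-MCI versus converter
  groups (e.g. a 12-item immediate recall at 10.5 ± 1.5 vs 8.5 ± 2.0, a
  48-item cued-recall total at 38 ± 6 vs 28 ± 8, intrusion counts higher
  in converters). Sampled scores are truncated to their valid ranges
  (MMSE to [0, 30], counts to ≥ 0) and count-like scores are rounded.
* Volumes are 16×16×16 by default — desk scale, but preserving the
  voxels ≫ subjects regime (4096 versus 46) that motivates the Gram
  trick. Converters lose mean intensity inside two axis-aligned
  ellipsoidal "hypometabolic" regions; the deficit is
  `effect_size_image · noise_sd`.
* The default image effect size is 0.5. This value was calibrated once so
  that an image-only classifier of the default cohort reaches ~70–78%
  leave-one-out accuracy — the operating point reported for FDG-PET alone
  in this setting — rather than a ceiling where fusion could not help.
* Every volume is multiplied by a per-subject log-normal global-uptake
  factor (SD 0.2 on the log scale) with a group-independent reference
  region, so cerebellar normalization is both necessary and sufficient to
  remove the nuisance.
* `effect_size_scores` overrides the converter means as
  stable_mean + direction·effect·SD, so `0` yields an exact null cohort;
  `NULL` (default) keeps the table values.

What the generator does *not* emulate: PET physics, partial-volume
effects, scanner noise spectra, anatomical atlases, or spatial
registration error. Passing tests therefore demonstrate the correctness
and calibration of the pipeline, not clinical performance on real data;
accuracies on synthetic cohorts are not comparable to published clinical
accuracies.

## Null-calibration design

With all effects at zero the group labels are exchangeable, so the
package's null experiments use balanced groups, where the majority-class
rate and chance coincide at 50%. This matters because a margin classifier
on z-scored features is balance-agnostic: under an imbalanced null its
leave-one-out accuracy centers on 50%, several points below the majority
rate (leave-one-out's well-known pessimism under the null), which would
conflate classifier bias with generator calibration.

## Problem sizes used by the test suite

The suite exercises full-size (46-subject, 16³) cohorts wherever a check
depends on the cohort shape — the separable end-to-end run, the null
accuracy calibration (23/23), the fusion-benefit comparison — and
8³-voxel cohorts with reduced grids (linear kernel, unit cost) for the
Monte-Carlo permutation replicates, where each draw reruns a complete
nested leave-one-out. These sizes are the package's choices for a
desk-scale test suite; all statistical thresholds are stated in the tests
themselves.

## Known limitations

* Binary classification only; no multi-class extension, kernel PCA or
  sparse variants.
* ROC pooling across LOO folds and the uniform (rather than resampled)
  permutation draws are conventions; alternatives exist and would change
  the numbers slightly.
* The intermediate strategy shares one kernel *kind* across the two
  sources (with its own weight); per-source kernel kinds would enlarge the
  search space beyond what 46 subjects support.
* `fit_on_all = TRUE` reproduces the (leakage-prone) variant in which the
  reduction basis is fitted once on all subjects; it exists for
  comparability and defaults to off.
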