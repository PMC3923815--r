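# neurofuse

Computer-aided diagnosis for early dementia: predicting which subjects with
mild cognitive impairment (MCI) will convert to Alzheimer's disease by
fusing two heterogeneous baseline measurements — an FDG-PET brain volume
and a panel of neuropsychological test scores (immediate recall, cued
recall, intrusions, phonemic and semantic fluency, optionally MMSE and
age).

The package is aimed at methodologists working on multimodal classifier
fusion in neuroimaging: every stage is an exported, tested function, and a
synthetic cohort generator stands in for the (non-deposited) clinical
database so the complete pipeline runs end to end on any machine.

## What it implements

1. **Preprocessing** — intensity normalization of each volume by the mean
   over a cerebellar reference mask, then flattening of brain-mask voxels
   into a subjects × voxels matrix.
2. **Dimensionality reduction** (small-sample regime, voxels ≫ subjects):
   * PCA via the N×N Gram-matrix ("eigenface") trick,
   * PLS against the class labels (NIPALS, X = T·Pᵀ + E),
   * ICA by seeded fixed-point nongaussianity maximization on PCA-whitened
     scores.

   Components are selected by cumulative importance: 75% of total variance
   (PCA) or 85% of the total Fisher discriminant ratio
   FDR = (μ₁−μ₂)²/(σ₁²+σ₂²) (PLS/ICA).
3. **Fusion** around an SVM with accessible decision values:
   * *early* — concatenation of the standardized score panel and image
     features, f_i = [p_i, g_i];
   * *intermediate* — multikernel classification,
     K = Σ_m β_m K_m with β_m ≥ 0, Σβ_m = 1, one kernel per source;
   * *late* — one classifier per source; the class whose decision value
     lies farther from its separating hyperplane wins
     (|d_I| vs |d_P|, ties to the individually more accurate source).
4. **Evaluation** — leave-one-out cross-validation with nested
   hyperparameter selection (everything refitted per fold), accuracy /
   sensitivity / specificity / LR± metrics, ROC and AUC from pooled
   decision values, and a permutation test: replace all scores by uniform
   draws over their observed ranges, rerun the full LOO, and report
   p = #{permuted accuracy > observed} / n_perm.

## Worked example

```r
library(neurofuse)

# a 46-subject cohort shaped like the reference study:
# 20 stable MCI / 26 converters, 16^3 volumes
cohort <- generate_cohort(synth_config(seed = 1))
fm <- vectorize_cohort(cohort)

hp  <- fusion_hyperparams(cost_grid = 1,
                          kernels = list(list(kind = "linear")))
cfg <- pipeline_config("pca", "early", use_mmse_age = TRUE,
                       hyperparams = hp, seed = 2)
rep <- loo_cross_validate(cohort, cfg, feature_matrix = fm)
rep
#> <evaluation_report> pca / early (+MMSE+age) — accuracy 89.13% |
#>   sensitivity 88.46% | specificity 90.00% | LR+ 8.85 | LR- 0.13
rep$roc$auc
#> [1] 0.9538462
```

The accuracy means 41 of the 46 held-out subjects were classified
correctly; sensitivity is the fraction of true converters detected (23 of
26), specificity the fraction of stable subjects recognized (18 of 20),
and the likelihood ratios summarize how much a positive/negative call
shifts the odds of conversion. For comparison, the same cohort gives an
image-only accuracy of 67.39% — the gain is the point of fusing in the
neuropsychological scores.

A YAML-driven command line (`inst/cli/neurofuse`) wraps the same
functions: `simulate`, `run` (the full approach × reduction grid with a
combined results table), `permtest`, `report`.

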