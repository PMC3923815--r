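Package: neurofuse
Title: Multimodal Fusion of PET Image Features and Neuropsychological Scores
    for Early Dementia Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-aided diagnosis pipeline for predicting conversion from
    mild cognitive impairment (MCI) to Alzheimer's disease by combining
    FDG-PET derived image features with neuropsychological test scores.
    Provides cerebellum-referenced intensity normalization, three
    dimensionality-reduction backends (Gram-trick PCA, label-guided partial
    least squares, fixed-point ICA) with cumulative variance / Fisher
    discriminant ratio component selection, three data-fusion strategies
    around a support vector machine (feature concatenation, weighted
    multikernel combination, decision-level fusion by margin distance),
    nested leave-one-out evaluation with confusion-derived metrics and ROC
    analysis, and a permutation test of the contribution of the
    neuropsychological scores. Includes a synthetic multimodal cohort
    generator so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    kernlab,
    e1071,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
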