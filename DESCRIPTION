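Package: mapquant
Title: Sequence-Adaptive Segmental Quantification of Liver Parametric MRI Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfers a multi-class Couinaud segmental label map from a
    thin-slice anatomical liver MRI acquisition onto arbitrary co-acquired
    parametric relaxation-time maps (T1, T2) through the scanner's shared
    physical coordinate frame, applies configurable quality-control gating
    (ROI erosion, minimum ROI size, median/MAD outlier removal, spatial
    entropy detection, normalized cross-correlation source-slice
    subselection), and computes volumetric segmental and total-liver ROI
    statistics. Includes inter-rater reliability analysis against reference
    measurements (one-way random single-measure intraclass correlation,
    Deming regression, Spearman correlation, paired Wilcoxon with bootstrap
    confidence intervals, agreement categorization), grid-search
    hyperparameter optimization of the quality-control configuration, and a
    synthetic phantom generator producing NIfTI exams with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
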