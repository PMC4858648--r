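Package: fmritex
Title: Radiomic Texture Analysis of fMRI Activation Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discriminates true ("expected") from false-positive or
    non-essential ("non-expected") fMRI activation clusters using
    gray-level co-occurrence matrix (GLCM) texture features computed on
    the mean echo-planar imaging volume. Provides per-slice GLCM
    construction over region-of-interest masks, the 20 classical
    rotation-invariant Haralick/Soh/Clausi texture features, anatomical
    cluster labeling, univariate group statistics, forward stepwise
    logistic regression with p-to-enter/p-to-remove thresholds and an
    AIC overfitting guard, patient-grouped repeated-holdout evaluation
    with ROC analysis, and synthetic-data generators (textured volumes
    and labeled feature tables) so that the full pipeline is testable
    without human scans.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
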