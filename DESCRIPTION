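Package: striatomics
Title: Radiomics Analysis of Striatal DAT-SPECT for Parkinson's Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volume-of-interest radiomics for spatially normalised
    dopamine-transporter SPECT. Computes striatal uptake ratios against an
    occipital background, a 930-dimensional IBSI-style radiomics feature
    vector (intensity, histogram, intensity-volume-histogram, local
    intensity, and GLCM/GLRLM/GLSZM/GLDZM/NGTDM/NGLDM texture families over
    caudate, putamen and pallidum plus caudate-ratio blocks), LASSO-based
    radiomics signature construction with ten-fold cross-validation, and a
    classifier/ROC evaluation harness with DeLong comparisons. Ships a
    synthetic MNI-grid phantom cohort generator so the full pipeline runs
    without access-restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    e1071,
    MASS,
    rpart,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC
Config/testthat/edition: 3
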