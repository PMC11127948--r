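Package: mfsedrn
Title: Multifeature Squeeze-and-Excitation Dilated Residual Networks for
    Longitudinal Alzheimer's Disease Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A 3D convolutional architecture for predicting longitudinal
    clinical scores (MMSE, ADAS-11) and MCI-to-AD conversion from structural
    MRI combined with tabular clinical, genetic and fluid-biomarker features.
    Provides the bespoke building blocks (multifusion pooling, dilated
    residual blocks with squeeze-and-excitation channel recalibration,
    image+tabular feature fusion), full model assembly with layer-census
    introspection and ablation variants, a hand-written training engine
    (backpropagation, Adam, L1/L2 regularization), repeated stratified
    k-fold evaluation, regression and classification metrics, and a fully
    synthetic ADNI-like cohort generator (phantom volumes with
    severity-linked focal atrophy plus calibrated tabular features and
    longitudinal targets) so the whole pipeline runs without protected data
    or a GPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
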