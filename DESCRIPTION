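Package: boldnine
Title: Voxel-Wise Summary Measures and 3D-CNN Classification of Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces 4D resting-state BOLD runs to nine voxel-wise temporal
    summary measures (ReHo, ALFF, fALFF, weighted degree and eigenvector
    centrality, local functional connectivity density, histogram entropy,
    voxel-mirrored homotopic connectivity, and lag autocorrelation), and
    classifies subjects (patient versus control) with a small 3D convolutional
    neural network and a linear-SVM baseline under single-measure, nine-channel,
    and majority-vote ensemble strategies. Provides five-fold and leave-site-out
    cross-validation with a shared stratified test set, Kendall agreement
    analysis between model predictions, occlusion-based attribution of
    performance to atlas regions, and a seeded multi-site synthetic BOLD cohort
    generator for end-to-end testing without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    e1071,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    stats,
    utils,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
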