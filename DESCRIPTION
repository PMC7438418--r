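Package: thoraxseg
Title: Slice-Wise Lung Segmentation for Thoracic CT with Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generic pipeline for automatic segmentation of the left and right
    lung in thoracic computed tomography: Hounsfield-unit preprocessing (body-region
    cropping, intensity windowing, slice rescaling), slice-wise semantic
    segmentation with U-net and residual U-net architectures trained by stochastic
    gradient descent on stratified mini-batches, volumetric reassembly with optional
    dense-area removal, and a full evaluation suite (Dice similarity coefficient,
    robust 95th-percentile Hausdorff distance, symmetric mean surface distance,
    tumour-overlap proportion, paired t-tests). A parametric synthetic
    thorax-phantom generator with consistent ground-truth masks supports
    development, testing, and desk-scale training-data-diversity experiments
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    withr,
    stats,
    utils,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
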