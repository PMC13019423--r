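Package: evspec
Title: Chemometric Analysis of AFM-IR Spectra from Extracellular Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric workflow for nanoscale infrared (AFM-IR) spectra of
    extracellular vesicles isolated by size-exclusion chromatography, polymer
    precipitation, and ultracentrifugation. Provides a calibrated synthetic
    spectrum generator built from pseudo-Voigt band templates, iterative
    polynomial (Lieber-type) baseline correction with total-intensity
    normalisation, PCA-based outlier screening via reduced Hotelling T2 and
    Q-residual statistics, PCA and hierarchical-cluster exploration, NIPALS
    PLS-DA with leave-one-out cross-validation, label-permutation testing and
    VIP scoring, pseudo-Voigt deconvolution of the albumin corona
    contribution, and resampling-based sample-size and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    minpack.lm,
    ape,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
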