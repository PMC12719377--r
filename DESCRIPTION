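Package: spectralseg
Title: Brain Tissue Segmentation from Dual-Energy CT Virtual Monoenergetic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of white matter, gray matter and cerebrospinal fluid
    from multi-energy (virtual monoenergetic) head CT volumes. Provides a
    synthetic multi-keV head-phantom cohort generator, U-Net and U-Net++
    convolutional backbones with spectral-fusion input pathways and an
    additive attention gate, a class-masked multi-class Dice loss with
    fold-based cross-validation training, ensemble slice-wise inference, and
    a full evaluation stack (Dice similarity coefficient, 95th-percentile
    Hausdorff distance, volume-difference statistics, leave-one-out jackknife
    confidence intervals and Welch tests with Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
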