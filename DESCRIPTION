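Package: GKDosePredict
Title: Isodose-Aware 3D Dose Regression and Plan-Quality Prediction for
    Gamma Knife Radiosurgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Lesion-level plan-quality prediction for Gamma Knife
    radiosurgery of brain metastases. Provides a seeded synthetic phantom
    generator that composes shot-based dose distributions from
    collimator-sized Gaussian kernels, a data-preparation pipeline that
    builds 3D tumor-space training samples, a plan-quality metric engine
    (coverage, selectivity, gradient index, CI50 and isodose-surface Dice
    scores), a composite training objective combining a weighted MSE with
    smoothed-Dice losses at the 100% and 50% isodose surfaces, a 3D
    hierarchically densely connected U-Net implemented with compiled
    direct-convolution kernels, sector-symmetry-respecting data
    augmentation, a
    cross-validated training loop, and a stratified statistical evaluation
    battery with paired Wilcoxon signed-rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
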