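Package: cfnet
Title: Confounder-Free Adversarial Feature Learning for Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end training of image-based predictors whose learned
    features are conditionally independent of measured confounding variables
    (age, sex, pubertal stage and the like). A confounder-prediction head is
    trained adversarially on an outcome-conditioned cohort using a
    squared-correlation surrogate loss, so that the feature extractor is
    driven toward mean independence between its features and each confounder
    given the outcome. The package provides the three-subnetwork model and
    its alternating min-max optimizer, cohort construction (outcome
    conditioning, full-width-at-half-maximum outcome intervals with
    bootstrapped matching, greedy confounder matching, confounder z-scoring),
    a statistical assessment toolkit (balanced accuracy and stratified
    metrics, post-hoc confounder probes, distance correlation,
    k-nearest-neighbour mutual information, bootstrap comparisons, gradient
    saliency maps), a synthetic confounded-image generator with known ground
    truth, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    RNifti,
    png,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
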