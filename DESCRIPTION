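Package: relmap3d
Title: Relevance Maps for 3D Convolutional Brain-Image Classifiers
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for explainable classification of 3D
    volumetric brain images. Implements a small fully convolutional 3D
    classifier trained with stochastic gradient descent, composite
    Layerwise Relevance Propagation (epsilon, alpha-beta and flat rules)
    with batch-normalization fusion and logit-mode model surgery, a
    quantitative validation battery for relevance maps (percentile
    binarization with Dice curves, normalized cross-correlation,
    region-wise aggregation, iterative occlusion with the area over the
    perturbation curve, and randomized null pipelines), longitudinal
    visit-history matching by optimal assignment, and progression-target
    construction with a nested cross-validated model-comparison suite.
    All components are exercised on synthetic ellipsoidal brain phantoms
    with planted lesions, so the full pipeline runs on a laptop CPU
    without any imaging downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
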