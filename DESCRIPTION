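Package: rsldecode
Title: Representational Similarity Learning for Neural Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes graded, multidimensional semantic structure from
    high-dimensional neural feature matrices (e.g. ECoG voltages) by
    representational similarity learning: a target similarity matrix built
    from semantic feature norms is decomposed into a low-rank embedding whose
    item coordinates are predicted from neural features by multitask linear
    regression regularized with the group ordered-weighted LASSO (grOWL) or
    the L1 norm, fit by accelerated proximal gradient descent. Includes a
    representational similarity analysis (RSA) baseline, synthetic-data
    generators for simulation studies, stratified nested cross-validation
    with Hyperband-style hyperparameter search, permutation-based null
    distributions with FDR control, and opening/moving temporal-window
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
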