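Package: refstream
Title: Reference-Condition Species Distribution Models for Stream
    Bioassessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits and compares three strategies for predicting stream fish
    assemblages at minimally disturbed reference sites: per-species
    ensembles screened with the true skill statistic, multi-species
    response models (multivariate adaptive regression splines and a
    single-hidden-layer neural network), and RIVPACS-style
    community-classification models built from flexible-beta clustering
    of Sorensen dissimilarities.  Sites are scored against the reference
    condition with observed/expected (O/E) taxonomic completeness and
    Bray-Curtis indices, and strategies are compared on accuracy,
    precision, bias and transferability.  A synthetic stream-assemblage
    generator with Gaussian and logistic niche responses to latent
    environmental gradients allows the whole pipeline to be exercised
    and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    nnet,
    randomForest,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
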