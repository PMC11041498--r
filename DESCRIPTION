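Package: patvec
Title: Self-Supervised Patient Embeddings from Claims Diagnosis Codes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Embeds complete ambulatory-claims diagnosis profiles into small
    real-valued vectors with a from-scratch Doc2Vec-style engine (distributed
    memory and distributed bag of words, negative sampling with a tunable
    smoothing exponent, hierarchical softmax, frequency downsampling, and
    unseen-patient inference). Ships a synthetic claims-cohort simulator with
    latent morbidity clusters and coupled outcomes, a top-M binary-encoding
    baseline, a 16-measure baseline-normalized calibration score over four
    health-care prediction tasks, hyperparameter search, diagnosis-dropout and
    training-size robustness experiments, and cohort exploration (2D
    projection, density clustering, overexpressed codes, code-dimension
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    xgboost,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
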