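Package: dkmeta
Title: Bayesian Meta-Learning with Deep Kernel Gaussian Processes for
    Few-Shot Reaction Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Few-shot prediction of reaction outcomes (high versus low
    enantioselectivity) with deep kernel Gaussian processes trained by
    meta-learning.  Implements deep kernel transfer (DKT), adaptive deep
    kernel fitting (ADKF), an ADKF variant with a Gaussian weight prior
    over the feature extractor (ADKF-prior), a prototypical-network
    baseline and a single-task deep kernel learning (DKL) baseline.
    Includes reaction featurization (circular and MACCS fingerprints,
    one-hot encodings, reaction conditions), construction of random,
    substrate-cluster leave-one-cluster-out and time-based meta-learning
    tasks, episode sampling, AUPRC evaluation, and a synthetic task
    generator that emulates the statistical structure of literature-mined
    asymmetric hydrogenation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    ChemmineOB,
    vegan
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
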