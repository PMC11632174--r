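Package: tldoe
Title: Transfer-Learning Bayesian Optimization for Competitor DNA Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Transfer-learning design-of-experiments workflow for tuning
    competitor DNA molecules to a target qPCR amplification rate under a
    drift penalty. Provides four Gaussian-process surrogate models (pooled
    AvgGP, independent-output MOGP, linear model of coregionalization, and
    a latent-variable multi-output GP trained by a variational bound), a
    target-vector expected-improvement acquisition with a probability-of-
    feasibility penalty, logistic amplification-curve fitting that extracts
    rate and drift from fluorescence traces, synthetic benchmark
    generators, and cross-validation and retrospective Bayesian-
    optimization harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
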