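Package: iaoadbn
Title: Improved Archimedes Optimization of Deep Belief Networks for
    Clinical Survival-Status Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for five-year survival-status classification on tabular
    clinical cohorts. Provides minimum-redundancy maximum-relevance (MRMR)
    feature ranking with binned mutual information, the Archimedes
    optimization algorithm (AOA) and an improved variant (IAOA) combining
    sine-chaos plus opposition-based initialization with Gaussian elite
    mutation, deep belief networks (DBN) pretrained by contrastive
    divergence, metaheuristic tuning of the DBN learning rate and batch
    size under stratified cross-validation, a registry of thirteen
    benchmark objective functions with run-matrix reporting, and a seeded
    generator of synthetic clinical cohorts with realistic marginal
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
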