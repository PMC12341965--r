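Package: synlogic
Title: Ensemble Boolean Logic Models for Drug Synergy Prediction
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assembles link-operator Boolean logic models from signed,
    directed prior-knowledge networks, calibrates model ensembles to
    steady-state biomarker profiles with a genetic algorithm (link-operator
    and topology mutations), exactly enumerates model fixed points,
    simulates single- and pairwise drug perturbations, scores
    Bliss-independence-style synergies with normalization against
    random-proliferative baseline ensembles, and benchmarks ranked synergy
    predictions (ROC/PR curves, bootstrap AUC comparison). Includes a
    synthetic-system generator with planted ground truth plus calibration
    corruption and topology-scrambling robustness experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
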