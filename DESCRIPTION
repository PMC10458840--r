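Package: felacc
Title: Behaviour Classification from Triaxial Accelerometers on Domestic Cats
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for identifying domestic cat behaviour from collar- and
    harness-mounted triaxial accelerometers. Simulates seeded synthetic
    accelerometer studies with known ground-truth behaviour sequences, reads
    ActiLife-style raw CSV and BORIS-style annotation exports, derives the 32
    per-epoch identifier variables (per-axis moment statistics, inter-axis
    correlations, vector-magnitude statistics and overall dynamic body
    acceleration), trains random-forest and supervised self-organizing-map
    classifiers per mounting location, runs an iterative behaviour
    merge/remove model-selection protocol, evaluates models with confusion
    matrices, per-class metrics and Cohen's kappa, and compares
    model-predicted daily activity budgets with log-link Dirichlet
    regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
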