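Package: seqrisk
Title: Deep Survival Modelling of Coded Health-Event Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Five-year cardiovascular risk prediction from longitudinal coded
    administrative health records, combining survival analysis with a recurrent
    neural relative-risk model. Provides a synthetic-cohort simulator with known
    planted hazard effects, sex-specific Cox proportional-hazards comparator
    models, a recurrent network (code/type embeddings, stacked bidirectional
    gated recurrent layers, dot-product attention) trained by maximizing the Cox
    partial likelihood with case-control mini-batches, Breslow-anchored absolute
    risk estimation, perturbation-based local hazard ratios, and an evaluation
    framework covering Harrell's C, the Royston-Sauerbrei D statistic and
    explained variation, the IPCW integrated Brier score, decile calibration
    tables, and cross-validated model comparison with combined 5x2 F tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    survival,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp, RcppArmadillo
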