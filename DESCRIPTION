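Package: tabsafe
Title: Privacy-Preserving Synthesis and Disclosure-Risk Evaluation of Tabular Health Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preparing, synthesizing, anonymizing and auditing mixed-type
    cohort tables such as biobank questionnaires and registries. Provides a
    bidirectional preprocessing pipeline for high-missingness data (median
    imputation, invertible empirical quantile transforms, missingness
    indicators, one-hot encoding), correlation- and distribution-aware loss
    functions with a Gaussian-copula reference generator, adaptive k-anonymity
    binning with exhaustive verification, an empirical disclosure-risk metric
    suite (k-anonymity, l-diversity, k-map, delta-presence, identifiability,
    membership inference, correct attribution probability, linkability,
    match rates), statistical-similarity and train-synthetic-test-real
    utility scoring, Friedman-Nemenyi model ranking with critical differences,
    data-sufficiency elbow analysis, and constraint-driven rejection sampling,
    orchestrated by a reproducible pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    e1071,
    nnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
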