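Package: sspva
Title: Simplified Symptom Pattern Method for Verbal Autopsy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assigns causes of death to verbal-autopsy records and estimates
    cause-specific mortality fractions (CSMFs) with the Simplified Symptom
    Pattern (SSP) method, a Bayesian classifier whose likelihood is the
    empirical probability of joint response patterns on clusters of
    dichotomous symptom items conditional on cause.  Covers the full
    twelve-variant design space (cluster size, single-cause versus
    multiple-cause models, all items versus tariff-selected top items,
    uniform versus King-Lu prior), King-Lu direct CSMF estimation,
    tariff-based item ranking, a synthetic verbal-autopsy population
    generator, Dirichlet-composition train/test validation splits, and the
    standard performance metrics: chance-corrected concordance, CSMF
    accuracy, Lin's concordance correlation by cause, and estimated-versus-
    true CSMF regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
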