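Package: radshoots
Title: Hierarchical Bayesian Analysis of Radiocesium in Hardwood Growing Shoots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing radiocesium activity concentrations measured in
    the growing shoots of coppice hardwoods. Fits hierarchical Bayesian
    log-normal models with random stand effects (optionally heteroscedastic
    across stands), species effects and a stem-origin covariate by Markov chain
    Monte Carlo, compares models with the widely applicable information
    criterion computed for prediction in a new stand, and provides the
    closed-form conjugate shrinkage machinery used to choose the number of
    shoots to sample per stand. Includes a synthetic-data generator matching
    the survey structure (40 stands, five species, left-censored detections)
    so the whole pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
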