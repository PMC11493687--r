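Package: erplocsim
Title: Simulated ERP Source Localization with Subject-Specific and
    Template Head Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation framework for quantifying how template head models
    degrade event-related potential (ERP) source localization relative to
    subject-specific head models.  Generates cohorts of multilayer spherical
    head models with an analytic leadfield solver, simulates multi-region ERP
    networks with pink noise calibrated to a target signal-to-noise ratio,
    reconstructs source activity per epoch with the eLORETA weighted
    minimum-norm inverse after noise pre-whitening, and scores the
    reconstructions with cluster-based sensitivity, precision, localization
    error and spatial dispersion metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
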