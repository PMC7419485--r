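Package: dyadVAR
Title: Vector Autoregression and Impulse-Response Analysis for Dyadic
    Behavioral Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for probing bidirectional influence in longitudinal
    mother-infant interaction studies. Aggregates coded behavioral event
    logs into equally spaced monthly multivariate panels, fits pooled
    vector autoregression (VAR) models with multivariate residual
    diagnostics and automatic lag selection, computes
    Cholesky-orthogonalized impulse-response functions (IRF) with
    residual-bootstrap confidence bands, runs the conservative
    "variable entered last" ordering sweep, and summarizes significant
    lagged effects as group-by-encoding sign tables. A synthetic
    dyad-cohort generator with known VAR(1) ground truth makes every
    stage of the workflow verifiable without access to real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
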