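Package: prcgait
Title: Phase Response Curves of a Neuromusculoskeletal Walking Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward-dynamic simulation of a sagittal-plane, seven-link,
    nine-muscle-per-leg human walking model on a treadmill, driven by
    muscle-synergy motor commands from coupled phase oscillators with
    optional foot-contact phase resetting, together with an impulse-method
    phase-response-curve (PRC) estimation pipeline.  Belt-speed impulses
    applied at swept gait phases are read out through Poincare-section
    event timing to estimate the PRC, and toy limit-cycle oscillators with
    known analytic PRCs validate the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
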