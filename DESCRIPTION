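Package: isosub
Title: Isotemporal and Compositional Isotemporal Substitution Modelling of
    Posture-Based Time Use
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the association of reallocating time between
    daily sitting, standing and stepping with standardised cardiometabolic
    outcomes. Implements the classical isotemporal substitution model (ISM:
    linear regression on behaviour durations with total waking wear time held
    fixed) and the compositional isotemporal substitution model (CISM:
    regression on isometric log-ratio coordinates of the behaviour
    composition, with reallocation effects predicted by perturbing a base
    composition). Includes valid-wear-day quality control for thigh-worn
    accelerometer summaries, clustered cardiometabolic risk score
    construction, a calibrated synthetic cohort generator for end-to-end
    testing, and an incremental-reallocation pipeline that contrasts the two
    methods' symmetry and linearity properties.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
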