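Package: maekin
Title: Kinetic Modelling of Microwave-Assisted Extraction of Mangiferin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the time course of microwave-assisted solid-liquid
    extraction (MAE) of mangiferin from plant matrices. Provides forward
    models (modified first-order kinetics, delayed logistic, and a
    design-variable-dependent generalized logistic), Levenberg-Marquardt
    nonlinear least-squares fitting with a dimensionless RMS/asymptote
    goodness-of-fit indicator, joint fitting of one-factor-at-a-time (OFAT)
    curve families by variable projection, balanced two-way analysis of
    variance with noncentrality and observed power, the Student-Newman-Keuls
    post hoc ranking, DPPH radical-scavenging IC50 estimation, and a
    synthetic-data generator that emulates the OFAT screening design so
    every pipeline stage is testable without raw instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
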