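Package: fracdyn
Title: Time-Resolved Modeling of Glioma Cell Response to Fractionated Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation, calibration, selection and validation of a
    two-compartment (proliferative/senescent) ordinary-differential-equation
    model of in vitro tumor-cell confluence under fractionated radiation.
    Includes exponential DNA double-strand-break repair kinetics with linear
    dose interpolation, an eight-member candidate model family combining
    early (acute) death, late (accumulation) death and senescence conversion,
    a fixed-step explicit Euler simulator, bounded Levenberg-Marquardt global
    least-squares calibration with Jacobian-based confidence intervals,
    corrected-AIC model selection with Akaike weights, delta-method prediction
    bands, Pearson and Lin concordance validation metrics, and a seeded
    generator of microscopy-like synthetic confluence datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
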