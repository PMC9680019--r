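Package: thermocal
Title: Temperature Correction of Process Spectra by Loading Space
    Standardization with PLS Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Chemometric toolkit for in situ solute concentration
    monitoring under varying temperature.  Implements loading space
    standardization (LSS), which models the temperature dependence of
    singular-value-decomposition loading vectors with second-order
    polynomials and uses the modelled loadings to transform a spectrum
    measured at one temperature so that it appears measured at a chosen
    reference temperature.  Includes single-response NIPALS partial least
    squares regression with random-subset cross-validation,
    Savitzky-Golay first-derivative preprocessing, a synthetic
    ATR-UV/mid-IR spectrum generator with Beer-Lambert concentration
    dependence and smooth temperature distortions, and workflow drivers
    for calibration-model comparison and solubility-curve determination
    from stepped-heating slurry experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    signal,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
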