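Package: irspeccalib
Title: Multivariate Calibration of ATR-IR Spectra by Hybrid PLS-LS-SVM
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A chemometrics pipeline for quantifying an analyte (iron in
    pharmaceutical formulations) from attenuated total reflectance infrared
    (ATR-IR) spectra against atomic absorption spectroscopy (AAS) reference
    values. Implements standard normal variate (SNV) preprocessing,
    Kennard-Stone calibration/test splitting, NIPALS partial least squares
    feeding a Gaussian-RBF least-squares support vector machine (PLS-LS-SVM),
    PRESS-based latent-variable selection, leave-one-out and leave-many-out
    cross-validation, external validation, and Y-permutation testing, together
    with a synthetic spectra generator for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
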