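Package: semgmass
Title: Estimating Appendicular Skeletal Muscle Mass from Surface EMG Amplitude Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for relating surface electromyography (sEMG) amplitude
    features to muscle strength and appendicular skeletal muscle mass (ASM).
    Provides the full analysis pipeline: a Gaussian-copula synthetic cohort
    generator calibrated to published marginal and correlation structure
    (including raw multi-electrode signal rendering), band-pass/rectify/RMS
    signal processing, per-maneuver feature extraction (MeanRMS, MaxRMS,
    RatioRMS, MVC strength), Pearson correlation tables, SPSS-style stepwise
    ordinary least squares with variance-inflation-factor and Durbin-Watson
    diagnostics, development/validation splitting with cross-validation, and
    the published fixed-coefficient ASM prediction equation with low-muscle-
    mass screening cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    signal,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    lmtest,
    Matrix,
    withr,
    optparse
Config/testthat/edition: 3
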