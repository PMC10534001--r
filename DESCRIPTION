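Package: ppgssc
Title: Multi-Site Photoplethysmography Scalogram Classification of Systemic Sclerosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening systemic sclerosis (SSc) from multi-site
    photoplethysmography (PPG) recordings collected under a three-phase
    baseline / arm-cuff occlusion / reactive-hyperaemia protocol. Provides a
    seeded synthetic cohort generator with class-dependent vascular dynamics,
    gain normalisation and signal-quality checks, continuous wavelet transform
    (generalized Morse wavelet) percent-energy scalogram images, a comparator
    discrete wavelet transform (Daubechies db4) feature pipeline, image and
    feature classifiers (a compact convolutional network trained from scratch,
    regularised linear discriminant analysis and k-nearest neighbours),
    participant-wise stratified cross-validation with leakage guards, and
    diagnostic-test evaluation with exact binomial confidence intervals and
    crosshair-plot data export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    class,
    png,
    withr
Config/testthat/edition: 3
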