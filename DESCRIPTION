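Package: fgar
Title: Fourier-Guided Attention Encoders for Histopathology Feature Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A transformer-style encoder for haematoxylin-eosin (H&E)
    histopathology tiles in which each block refines patch tokens in the
    spatial-frequency domain before self-attention: patch tokens are laid out
    on their two-dimensional grid, transformed with a 2-D FFT, recalibrated
    per channel by a squeeze-and-excitation gate computed from spectral
    magnitudes, inverse-transformed and added back residually.  The package
    provides end-to-end training with AdamW and cross-entropy, a
    feature-extraction mode exporting the class token, configurable ablation
    variants of the spectral block, five handcrafted texture descriptor
    baselines (colour histogram, luminance histogram, HOG, LBP, GLCM), a
    unified downstream evaluation protocol with seven shallow classifiers,
    and a synthetic two-class H&E-like texture generator whose class signal
    has a controlled spectral component, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
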