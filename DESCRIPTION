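Package: mweeg
Title: Estimating Mind-Wandering Intensity from EEG Band Power and Coherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for regressing the intensity of mind-wandering,
    reported on a 7-point Likert scale during a sustained-attention task, on
    scalp EEG spectral features. Raw multichannel recordings are band-pass and
    notch filtered, cut into 1-s epochs, screened for artifacts, and summarized
    per task section as band power and magnitude-squared coherence in eight
    frequency bands. Predictors are screened by a correlation filter over a
    grid of thresholds and fed to epsilon-insensitive support vector
    regression (linear and radial-basis kernels) tuned by 10-fold
    cross-validated grid search, including model variants restricted to a
    small electrode budget. Held-out accuracy is compared across models with
    correlation tests and dependent-correlation difference tests. A synthetic
    cohort generator with a latent autoregressive mind-wandering process and
    planted, parameterized effect pathways provides ground truth for
    end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    kernlab,
    signal,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nloptr,
    withr
Config/testthat/edition: 3
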