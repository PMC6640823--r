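Package: cardiofluor
Title: Label-Free Autofluorescence Lifetime and Diffuse Reflectance Analysis
    of Myocardium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free optical monitoring of cardiac
    tissue: time-correlated single photon counting (TCSPC) autofluorescence
    decay analysis with multi-exponential instrument-response reconvolution,
    incomplete-decay (high repetition rate) and detector afterpulsing
    corrections, intensity-weighted mean lifetimes, spectral-channel
    intensity fractions, diffuse-reflectance absorbance with white-reference
    calibration, and cohort statistics (Welch's t-test with Holm-Sidak
    step-down adjustment and Cohen's d).  A synthetic-data generator emulates
    the measurement structure of an in vivo rat myocardial-infarction study
    (four spectral detection channels at 20 MHz excitation, three positions
    by three repeats per region of interest) so that every stage of the
    pipeline can be exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    knitr
Config/testthat/edition: 3
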