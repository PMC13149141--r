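Package: crvcoupling
Title: Cardio-Respiratory-Vascular Coupling Analysis of Synchronous
    Physiological Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies dynamic coupling among cardiac, respiratory, and
    vascular oscillations from synchronous ECG, respiratory-effort, and
    continuous blood-pressure recordings. Implements preprocessing (notch
    and band-pass conditioning, R-peak and pulse-landmark detection,
    ectopic-beat exclusion, cubic-spline resampling), a multimodal coupling
    engine (ensemble empirical mode decomposition, Hilbert instantaneous
    phase, sliding-window phase synchronization, refined composite
    multiscale entropy, composite strength and complexity indices), heart
    rate variability and respiratory-pattern feature extraction, cohort
    statistics (one-way ANOVA with Bonferroni-corrected pairwise
    comparisons, Spearman rank correlation), and a fully parameterised
    synthetic-record generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
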