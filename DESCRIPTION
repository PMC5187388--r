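Package: adaptsr
Title: Adaptive Stochastic Resonance Modelling of Auditory Detection Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-frequency-channel model of the auditory periphery in which
    internal noise is tuned by adaptive stochastic resonance. Provides an
    Ornstein-Uhlenbeck generator for Gaussian, temporally autocorrelated
    sound-intensity trajectories; an infomax rate-intensity sensor with
    threshold, spontaneous and maximum firing rates; autocorrelation and
    mutual-information objectives; resonance-curve grid search and a
    closed-loop noise controller; psychometric and iso-autocorrelation
    estimators of the detection-threshold benefit conferred by optimally
    tuned noise after simulated hearing loss; and a synthetic audiometric
    cohort module with per-frequency two-sample Kolmogorov-Smirnov group
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
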