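Package: gecibench
Title: Benchmarking Analytics for Genetically Encoded Calcium Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A verifiable pipeline for quantifying calcium-indicator
    performance from fluorescence time series: neuropil-corrected dF/F0
    extraction, visual-responsiveness classification and orientation-tuning
    fits, transient kinetics (half-rise/half-decay, exponential fits,
    stimulus-tracking Fourier amplitude), template-projection spike
    detection with d-prime and ROC analysis, depth-attenuation fitting,
    and culture-screen variant comparison. A spike-to-fluorescence forward
    model with known ground truth drives every stage so each estimator is
    testable by parameter recovery and closed-form oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
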