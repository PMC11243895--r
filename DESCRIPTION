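Package: hrvfatigue
Title: Driver Fatigue Detection from Short-Segment Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for detecting driver fatigue from 2-minute
    electrocardiogram (ECG) segments. Provides a synthetic cohort generator
    (RR-interval series with autonomic-band modulation, template ECG waveforms,
    and simulated per-minute expert mental-state ratings), R-peak detection and
    RR-series construction, overlapping 2-minute windowing with expert-consensus
    labelling, a battery of twenty heart rate variability features spanning
    time-domain, frequency-domain and nonlinear methods (including sample and
    approximate entropy, detrended fluctuation analysis and correlation
    dimension), sex-stratified Mann-Whitney group comparisons, and a
    from-scratch CART decision-tree classifier with exhaustive feature-subset
    search and confusion-matrix performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
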