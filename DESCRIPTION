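Package: critaval
Title: Neuronal Avalanche Detection and Criticality Metrics for
    Multi-Channel Spike Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for neuronal avalanches in multi-channel
    spike recordings: population-activity binning, threshold-based
    avalanche detection, truncated discrete power-law fitting of size and
    duration distributions by maximum likelihood with Kolmogorov-Smirnov
    model selection and surrogate hypothesis testing, and three
    criticality metrics (deviation-from-criticality coefficient,
    subsampling-corrected branching ratio, avalanche shape-collapse
    error). Includes burst-pattern classification, heteroscedastic group
    comparisons, cross-validated session-state classification, 2-D
    embedding of session feature vectors, and a driven branching-process
    simulator so that every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
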