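Package: somnocohort
Title: Wearable-Derived Sleep Metrics, PSQI Scoring and Sleep-Phenotype
    Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for digital phenotyping of sleep in population cohorts
    tracked with consumer wearables. Parses Fitbit-style JSON sleep and
    activity logs, applies day-completeness quality control, derives
    per-volunteer total sleep time, sleep efficiency, nocturnal awakening
    counts and circular-mean sleep/wake clock times, scores the Pittsburgh
    Sleep Quality Index (PSQI), runs a covariate-adjusted Gaussian GLM
    association battery against cardiovascular risk markers and leukocyte
    telomere length, implements qPCR T/S-ratio telomere arithmetic
    (standard curves, triplicate handling, interplate normalization, batch
    adjustment), and generates fully synthetic cohorts with planted,
    configurable effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
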