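Package: gazentropy
Title: Gaze Transition Entropy and Bayesian Mediation Analysis of Spatial Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing visual exploration during spatial learning from
    eye-tracking scanpaths. Classifies raw gaze samples into fixations with an
    adaptive velocity threshold (with translational-movement correction for
    walking observers), builds forward transition matrices over visual
    categories, and computes Chao-Shen coverage-corrected, stationary-weighted,
    normalized gaze transition entropy (GTE). Extracts non-overlapping 30-second
    pre/post windows time-locked to agent encounters, fits Bayesian hierarchical
    Gamma and Beta regressions (via JAGS) for dwelling time, entropy dynamics and
    pointing performance, and estimates natural direct, indirect and total
    effects of agent context on pointing error through GTE by Bayesian
    parametric g-computation. Includes a synthetic-data generator emulating
    category-labelled fixation sequences from condition-specific Markov chains,
    Gamma dwell durations, agent encounters and pointing trials, so that the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    coda,
    rjags,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    withr
Config/testthat/edition: 3
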