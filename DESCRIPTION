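Package: metaconf
Title: Type-2 Signal Detection Analysis of Perceptual Confidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of staircase-controlled two-interval
    forced-choice confidence experiments across sensory modalities. Implements
    the continuous 2-down/1-up adaptive staircase, type-1 (d-prime) and type-2
    (meta-d-prime) signal detection estimation by maximum likelihood and
    single-subject Bayesian fitting, metacognitive efficiency measures
    (meta-d'/d' and meta-d' - d'), hierarchical Bayesian estimation of the
    cross-task correlation of metacognitive efficiency, Bayes factors for
    Pearson correlations (stretched-beta prior) and paired t-tests (JZS Cauchy
    prior), Steiger's Z for overlapping dependent correlations, a sequential
    Bayes-factor stopping rule, a synthetic-cohort generator emulating a
    three-modality (visual contrast, innocuous warmth, noxious heat) intensity
    discrimination study, and an end-to-end analysis pipeline with exclusion
    rules and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
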