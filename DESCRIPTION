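Package: enshue
Title: Simulation and Analysis of Hue Ensemble Perception Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing two-interval forced-choice
    experiments on ensemble perception of hue. Provides circular (hue-circle)
    statistics and von Mises probability machinery, parametric stimulus and
    trial-schedule generators for ensemble-comparison designs with distractor
    distributions, synthetic observers that mix target and distractor signals
    with internal noise, maximum-likelihood fitting of cumulative Gaussian
    psychometric functions (bias and discrimination threshold), a von Mises
    category-boundary observer model with maximum-likelihood boundary
    estimation, interleaved adaptive staircases for category-boundary
    localisation, and condition-level statistics (paired t tests, Bonferroni
    correction, Pearson correlations) over fitted observer measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
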