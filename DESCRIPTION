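Package: cmsm
Title: Correlated Multistate Models with Shared Gamma Frailties for Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time, reversible Markov multistate models for two
    disease processes observed at irregular clinic visits (panel data), coupled
    within subject by a shared gamma-distributed random effect (frailty) that
    acts multiplicatively on the transition intensities through configurable
    link functions. Models are fitted by maximum likelihood with the frailty
    integrated out numerically; the package also provides empirical Bayes
    estimates of subject-level frailties, expected state-occupancy times over a
    fixed horizon (single-process and joint states; conditional on the frailty,
    averaged over its distribution, or by Monte Carlo), exact simulation of
    synthetic cohorts, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
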