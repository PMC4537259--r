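Package: phenodisc
Title: Gaussian-Overlap Discrimination and Penetrance Statistics for
    High-Dimensional Behavioral Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-group discrimination of high-dimensional
    behavioral feature tables, as produced by automated rodent phenotyping
    platforms. Features are z-scored, decorrelated by pooled-covariance
    whitening, and ranked by standardized group difference; per-group
    Gaussian clouds are fitted in the top-ranked plane and their overlap
    coefficient defines a discrimination index, with a randomized-label
    resampling null providing a chance p-value. Also implements a
    per-subject mean-absolute-z penetrance statistic with permutation tests
    on group mean and variability, speed- and weight-adjusted gait
    regressions with between-group line comparison, and a synthetic cohort
    generator with block-correlated features, latent trait correlation and
    incomplete penetrance for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
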