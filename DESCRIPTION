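Package: mbetat
Title: Weighted Beta-Binomial t-Tests for Differential Expression from
    Small-Sample RNA Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential expression testing for gene- or isoform-level read
    count matrices with few replicate libraries, using a weighted
    beta-binomial model of per-library proportions. Per-feature t-statistics
    are stabilised by a floored variance estimator and then shrunken or
    inflated by a gap factor (the geometric mean of a polar ratio and a
    noise-moderated log odds ratio) relative to a threshold calibrated on
    simulated null data, which suppresses the small-sample fudge effect
    that otherwise inflates t-statistics for features with tiny within-group
    variances. Includes a negative-binomial scenario simulator with
    ground-truth labels, a null-simulation calibration routine for the
    shrinkage threshold, and an evaluation harness reporting power, true
    false discovery rate, efficiency, ROC points and stability order scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
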