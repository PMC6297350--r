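Package: ringbias
Title: Sampling Bias in Tree-Ring Networks and Its Consequences for
    Climate-Growth Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying how targeted
    (climate-signal maximizing) tree-ring sampling differs from
    representative forest-inventory sampling in growth variability,
    climate sensitivity, and projected future growth.  Includes a
    synthetic-landscape generator with configurable macro-site, micro-site,
    and age selection biases, Tucson (.rwl) ring-width input/output,
    negative-exponential and frequency-cutoff spline detrending with
    optional autoregressive prewhitening, per-tree climate-sensitivity
    regression, geographically local bootstrapped rank-sum contrasts,
    geographically weighted and variance-stabilized regional chronologies,
    and linear climate-growth projection under future climate normals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
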