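Package: tidymr
Title: Tidy Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for two-sample Mendelian randomization
    (MR) on GWAS summary statistics. Provides validated readers and writers for
    summary-statistic tables, fixed-effects inverse-variance meta-analysis with
    genomic-inflation and LD score regression diagnostics, genetic instrument
    selection with greedy LD clumping and allele harmonization, four causal
    estimators (inverse-variance weighted with fixed or multiplicative
    random effects, MR-Egger regression, the weighted median estimator, and
    the mode-based estimator), a sensitivity battery (Cochran and Rucker
    heterogeneity statistics, radial outlier detection, leave-one-out series,
    Steiger directionality, concordance classification), polygenic-score style
    association at relaxed thresholds, analytic power calculation, and an
    end-to-end study pipeline. Ships a seeded synthetic-data generator for
    two-sample summary statistics with known causal truth, configurable
    horizontal pleiotropy, per-consortium splits, and block LD panels, so the
    whole machinery can be validated against simulations with known answers.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
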