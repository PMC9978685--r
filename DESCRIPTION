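Package: tidymr
Title: Tidy Two-Sample Mendelian Randomization with Meta-Analysis and
    Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for two-sample Mendelian
    randomization from GWAS summary statistics: reading and harmonizing
    variant-level association tables, per-variant Wald ratios,
    inverse-variance weighted combination with Cochran heterogeneity
    statistics, pleiotropy-robust estimators (MR-Egger, weighted median,
    weighted mode), DerSimonian-Laird random-effects meta-analysis across
    studies, and two-step network mediation analysis with bootstrap
    uncertainty. Includes a summary-statistic simulator with configurable
    causal effects, pleiotropy and mediation structure so every pipeline
    stage can be validated against known truth, and a study orchestrator
    that runs the full analysis from a single configuration.
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
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
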