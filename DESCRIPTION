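Package: tsmr
Title: Two-Sample Mendelian Randomisation from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation with GWAS
    summary statistics: reading and validating summary-statistic tables,
    allele harmonisation with palindrome handling, LD clumping against a
    user-supplied correlation matrix, instrument-strength F-statistics and
    Steiger directionality filtering, causal estimation by Wald ratio,
    inverse-variance weighting, MR-Egger regression, weighted median and
    weighted mode, and a full sensitivity suite (Cochran's Q, Egger
    intercept test, leave-one-out, single-SNP forest and funnel data).
    Includes a generator of paired synthetic exposure/outcome summary
    statistics with known causal effect, configurable horizontal
    pleiotropy, LD blocks and binary outcomes, so every pipeline stage is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
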