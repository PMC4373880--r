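Package: anova2x2
Title: Sums-of-Squares Decomposition and Power Analysis for Unbalanced 2x2 Factorial Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 2x2 factorial experiments with unequal cell
    counts. Provides a from-scratch nested least-squares engine for Type I, II
    and III sums of squares under treatment (0,1) or sum-to-zero (-1,1)
    coding, a commonality (Venn) decomposition of the regression sum of
    squares into seven unique and cross-predictive components, enumeration of
    cell-count patterns with an imbalance indicator, synthetic data generation
    under two effect-construction schemes, and a paired Monte-Carlo power
    study comparing rejection rates in unbalanced designs with their balanced
    counterparts, validated against a closed-form noncentral-F oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
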