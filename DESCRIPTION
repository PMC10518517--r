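Package: bidirmr
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for bidirectional two-sample Mendelian
    randomization (MR) between circulating biomarkers and a binary disease
    trait. Reads and validates GWAS summary-statistic tables, converts
    BOLT-LMM linear-scale effects for binary traits to log odds ratios,
    selects independent and strong genetic instruments (p-value thresholding,
    LD clumping against a local reference, F-statistic filtering,
    confounder/outcome Bonferroni screens, LD proxy substitution), harmonizes
    exposure and outcome effect alleles with strand correction and palindrome
    exclusion, and estimates causal effects by Wald ratio, inverse-variance
    weighting with multiplicative random effects, MR-Egger, weighted median,
    and weighted mode. Sensitivity analyses include Cochran's Q and I-squared
    heterogeneity statistics, leave-one-out, funnel-plot data, and a
    simulation-based residual-sum-of-squares outlier framework with global,
    per-variant, and distortion tests. A synthetic summary-statistic generator
    with known causal effects, pleiotropy regimes, LD blocks, and allele
    encoding quirks makes every pipeline stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
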