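Package: multicause
Title: Weighted Multiple-Cause-of-Death Mortality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cause-specific mortality surveillance that use every
    condition recorded on the death certificate rather than the underlying
    cause alone. Implements fractional cause-of-death weighting (half weight
    to the underlying cause with the remainder split across Part II
    contributing causes, or equal shares across all mentions), ICD-10 cause
    grouping with COVID-19 and ill-defined handling, single imputation of
    missing sex and age, directly age-standardized mortality rates with
    Fay-Feuer gamma confidence intervals, and standardized rate differences
    and ratios contrasting multiple-cause with underlying-cause estimates.
    A synthetic death-certificate generator with closed-form expected rates
    makes the whole pipeline testable end to end.
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
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
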