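Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A case/non-case pharmacovigilance pipeline for FDA Adverse Event
    Reporting System (FAERS) style quarterly ASCII extracts: report parsing and
    FDA-rule deduplication, drug-name normalisation and MedDRA-style PT-to-SOC
    aggregation, descriptive cohort summaries, and four disproportionality
    algorithms on 2x2 contingency tables (reporting odds ratio, proportional
    reporting ratio with Yates chi-square, the BCPNN information component, and
    the empirical-Bayes gamma-Poisson shrinker EBGM) together with their
    conventional signal criteria, Benjamini-Hochberg adjusted volcano
    coordinates, a contingency-table reconstruction oracle for published
    summary rows, and a synthetic FAERS-like report generator with planted
    reporting-rate multipliers for end-to-end validation.
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
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
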