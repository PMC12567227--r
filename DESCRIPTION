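Package: pvsignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for spontaneous adverse-event report
    databases distributed in the FAERS quarterly file layout. Reads the public
    dollar-delimited ASCII dialect (demographics, drug and reaction files),
    normalizes drug names against a generic/brand synonym vocabulary,
    deduplicates case records on the (primary ID, drug, route, dosage) key,
    applies MedDRA preferred-term filter sets over per-drug extraction windows,
    builds 2x2 contingency tables and computes reporting odds ratios (ROR),
    proportional reporting ratios (PRR) and the Bayesian Information Component
    (IC) with 95 percent intervals, together with Fisher's exact test and
    chi-square tests with and without Yates' continuity correction. A synthetic
    report generator with planted association strengths, injected duplicates
    and brand-name synonym noise makes every stage testable end to end without
    any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
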