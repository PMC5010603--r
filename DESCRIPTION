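Package: hepatosafe
Title: Hepatotoxicity Surveillance Pipelines for Anti-VEGF New-User Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A common-protocol pharmacoepidemiology pipeline for surveillance
    of drug-induced liver injury among new users of anti-VEGF therapies
    (pazopanib, sorafenib, sunitinib, bevacizumab) in renal cell carcinoma.
    Provides a relational electronic-medical-record data model with CSV
    readers and validation, a seeded synthetic EMR generator, new-user
    cohort selection, treatment-episode (drug-era) construction with gap
    stitching and alternate-treatment truncation, liver-chemistry elevation
    classification against a catalog of ULN-multiple thresholds, Hy's-law
    and DILI screening, and censored person-time incidence estimation with
    exact binomial and Poisson confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
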