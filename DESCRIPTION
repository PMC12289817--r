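Package: tmascore
Title: Four-Tier Immunohistochemistry Scoring and Tissue-Microarray Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing immunohistochemistry (IHC) staining readouts
    from tissue-microarray (TMA) cohorts. Implements a four-tier categorization
    of staining results (negative, weak, moderate, strong) from pathologist
    readouts of staining intensity (0-3) and percentage of positive neoplastic
    cells, per-entity prevalence tables and positivity rankings, chi-square
    association testing between staining category and tumor phenotype,
    Kaplan-Meier and log-rank survival comparison with covariate-adjusted
    proportional-hazards fits, and dichotomization of expression values by
    z-score against a normal reference. A synthetic-cohort simulator generates
    multi-entity TMA cohorts with configurable category prevalences,
    non-interpretable dropout, phenotype-linked ordinal shifts, and
    category-dependent hazards, so the whole pipeline can be exercised and
    validated without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
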