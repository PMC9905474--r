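Package: irscore
Title: Immunotherapy Response Score Modelling from Real-World Oncology Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for deriving real-world treatment lines and survival
    endpoints (time-to-next-therapy progression-free survival and overall
    survival) from per-dose medication records, normalizing targeted
    expression panels to normalized reads per million, scoring patients
    with a locked Immunotherapy Response Score (a linear combination of
    log2 tumor mutation burden and centered log2 expression of PD-1,
    PD-L1, ADAM12 and TOP2A), re-deriving the score by cross-validated
    Lasso-penalized Cox regression, and validating it with Kaplan-Meier,
    adjusted Cox, restricted mean survival time, interaction and
    propensity-matching analyses. Includes a seeded synthetic-cohort
    generator with Gaussian-copula biomarkers and proportional-hazards
    outcomes so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    survival,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
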