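Package: copdpersist
Title: Persistence and Switching Analysis of Inhaled COPD Medication from
    Pharmacy Dispensing Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying chronic obstructive pulmonary disease (COPD)
    patients' persistence with long-acting beta2-agonist (LABA) inhalers using
    pharmacy dispensing records. Implements a new-user cohort selection cascade
    with an auditable exclusion flow, the refill-gap method for treatment
    persistence (coverage intervals from units dispensed divided by prescribed
    daily dose, with configurable gap threshold and carry-over of surplus
    supply), classification of post-discontinuation switching and restarting
    behaviour by inhaler device and medication class, ATC-proxy comorbidity
    covariates, and cohort-comparison statistics (Fisher's exact and
    Mann-Whitney screening, Kaplan-Meier curves, Cox proportional hazards).
    A synthetic dispensing-data generator with recorded ground truth makes the
    whole pipeline testable without access to a proprietary claims database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
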