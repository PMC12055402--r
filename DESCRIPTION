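Package: hcmburden
Title: Disease-Burden Analysis of Obstructive Hypertrophic Cardiomyopathy
    from Linked Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for quantifying the clinical and
    economic burden of obstructive hypertrophic cardiomyopathy (HCM) from
    linked primary-care (CPRD GOLD/Aurum-like) and secondary-care (HES-like)
    electronic health records. Implements cohort construction with index-date
    and eligibility rules, a proxy New York Heart Association (NYHA)
    functional-class decision tree applied at baseline and daily over
    follow-up with an asymptomatic-correction ratchet, prescription-episode
    construction and a treatment-change taxonomy, person-time incidence of
    clinical events stratified by time-varying NYHA class, Kaplan-Meier
    time-to-event curves, healthcare-resource costing with unit-cost and HRG
    tables, and reporting with small-cell disclosure suppression. A seeded
    synthetic EHR generator with a latent severity process makes every stage
    testable without access to licensed data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    jsonlite,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
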