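Package: engage
Title: Parent Engagement Scoring for Asymmetric Family-Based
    Interventions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies parent engagement in school- and family-based
    youth health interventions with unbalanced designs. Builds activity
    catalogs whose intensity factors are derived from five burden
    attributes, scores participation logs into Parent Participation
    Profile (PPP) and Parent Engagement Intensity (PEI) indices with
    study-arm-specific standardization, classifies positive deviants,
    and provides the accompanying analysis surface (two-group
    comparisons, categorical association, engagement-outcome
    correlation, BMI-percentile adjustment for school and classroom, and
    two-timepoint repeated measures). A seeded synthetic-cohort
    generator emulates arms with unequal offerings, burden-dependent
    uptake, and configurable engagement-BMI dependence.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
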