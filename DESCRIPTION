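Package: pimscreen
Title: Screening Dispensing Claims of Older Adults for Potentially
    Inappropriate Medications
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects potentially inappropriate medications (PIMs) in
    ATC-coded drug-dispensing claims of adults aged 65 and over, using a
    machine-readable rule catalog derived from the 2019 American Geriatrics
    Society Beers Criteria (avoid / use-with-caution / strong-anticholinergic
    categories, with ticlopidine retained for markets where it is still
    reimbursed).  Applicability conditions are operationalized for claims
    data: consecutive-dispensation gap screening for use beyond 8 weeks,
    90-day co-dispensing windows, unit-dose limits, chronic use defined as 5
    or more dispensations per year, and route/form keywords parsed from
    medication names.  Includes cohort eligibility and age stratification,
    annual prevalence and ranked frequency reporting, anticholinergic
    cognitive burden (ACB) scoring of chronic users, and a seeded synthetic
    claims generator with exact ground-truth labels for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
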