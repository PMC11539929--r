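Package: agitAD
Title: Claims-Based Identification and Healthcare Burden Analysis of
    Agitation in Alzheimer Dementia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a computable-phenotype pipeline over longitudinal
    administrative claims for studying agitation in Alzheimer dementia:
    diagnosis confirmation with temporal spacing rules (two or more claims
    30 or more days apart for Alzheimer's disease and for dementia; 14 or
    more days for agitation), index-date determination, continuous-enrollment
    checks, severe-mental-illness exclusion, and cohort attrition reporting.
    Downstream modules construct institutional stays from claims and compute
    healthcare-resource-utilization measures (annualized rates per 100
    members per year, length of stay per patient and per stay, 30-day
    readmission, post-acute care by setting), per-patient-per-year costs by
    category, and baseline cohort profiles including the Charlson
    Comorbidity Index. A seeded synthetic claims generator with planted
    per-beneficiary ground truth stands in for restricted Medicare
    Fee-for-Service data so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
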