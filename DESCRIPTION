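Package: hospcomp
Title: Hospital Outcome Profiling with an Ordinal Composite Measure and
    Rankability
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing hospitals on in-hospital mortality, 30-day
    unplanned readmission and prolonged length of stay from admission-level
    administrative data.  Provides per-group logistic case-mix models with
    backward elimination and sparse age-group merging, indirectly
    standardized outcome ratios (100 x observed/expected), patient-level and
    hospital-level correlation analyses, a five-level ordinal composite
    outcome analysed by proportional-odds regression with hospital fixed
    effects, and the rankability statistic that separates true
    between-hospital variation from estimation noise.  Includes a synthetic
    admission-cohort generator with planted hospital effects and
    configurable patient-level couplings for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
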