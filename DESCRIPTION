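Package: lynchcohort
Title: Prospective Penetrance and Survival Estimation for Lynch Syndrome
    Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A carrier-centric computation engine for prospective cohorts of
    mismatch-repair (MMR) gene variant carriers. From three plain-text tables
    (carriers, follow-up windows, cancer events) it computes age-cohort event
    counts, person-years and annual incidence rates under arbitrary filters
    with left truncation and right censoring; exact (Garwood) Poisson
    confidence intervals; cumulative cancer incidence from any current age
    with parametric-bootstrap confidence bands; Kaplan-Meier-ready
    time-to-event exports with a reference product-limit estimator; and
    cohort summary counts. A synthetic-cohort simulator with known
    piecewise-constant annual hazards supports testing and methods work
    without access to confidential registry data. Includes a command-line
    interface for reproducible, logged runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
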