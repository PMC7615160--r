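Package: cvdimpact
Title: Quality-of-Life and Hospital-Cost Impacts of New Cardiovascular and
    Nonvascular Events in Secondary Prevention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how new vascular and nonvascular events
    (myocardial infarction, stroke, coronary and noncoronary
    revascularisation, heart failure admission, incident cancer and
    diabetes, vascular and nonvascular death) affect health-related
    quality of life (EQ-5D-5L utilities) and annual hospital costs in a
    secondary-prevention cohort.  Implements EQ-5D-5L profile scoring
    under pluggable value sets, hierarchical temporal event-history
    covariates on last-occurrence (quality of life) and first-occurrence
    (cost) clocks, hospital-episode merging and annual cost aggregation,
    a Gaussian linear model for final quality of life adjusted for
    baseline utility, a two-part generalized linear model for annual
    hospital costs (logistic for any cost; identity-link gamma for cost
    magnitude, with admissions certain for revascularisation and heart
    failure event years) with cluster-robust standard errors, covariate
    selection, F-test merging of adjacent temporal categories, and
    interaction screening for co-occurring events.  Incremental annual
    costs are obtained by recycled prediction with cluster-bootstrap
    confidence intervals.  A calibrated synthetic cohort generator
    reproduces the statistical structure the analysis assumes and
    supports end-to-end testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
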