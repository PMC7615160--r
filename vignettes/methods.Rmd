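---
title: "Modelling event impacts on quality of life and hospital costs"
author: "cvdimpact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling event impacts on quality of life and hospital costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdimpact)
```

## The problem

Patients with established cardiovascular disease remain at high risk of
further vascular events even under good risk-factor control.
Decision-analytic models of secondary-prevention therapies need two
ingredients that are hard to obtain: how much a new event (myocardial
infarction, stroke, a revascularisation procedure, a heart-failure
admission, incident cancer or diabetes, or death) reduces health-related
quality of life, and how much additional hospital cost it generates — in
the event year and in the years after.  `cvdimpact` implements a
complete, tested pipeline for estimating both from participant-level
trial-style data: EQ-5D-5L scoring, temporal event-history construction,
a Gaussian linear model for final-visit utility, a two-part GLM for
annual hospital costs with cluster-robust inference, and
recycled-prediction incremental costs with cluster-bootstrap intervals.
A calibrated synthetic cohort generator provides data with the exact
statistical structure the analysis assumes, so every estimator can be
checked against known generating values.

## Quality-of-life utilities

EQ-5D-5L describes a health state by five dimensions (mobility,
self-care, usual activities, pain/discomfort, anxiety/depression), each
at levels 1–5.  A value set (tariff) maps a profile to a utility:
1 is full health, 0 is a state equivalent to death, negative values are
worse than death.  We implement the additive decrement form
$u = 1 - c\,[\text{any problem}] - \sum_d \delta_{d,\ell_d}$ with
$\delta_{d,1}=0$, which covers the UK, US and Chinese value-set
families.  Licensed value-set coefficients are not redistributed: users
load them as CSV through `read_tariff()`.  The bundled tariffs
(`eq5d_tariff("toy")`, `"synthetic_uk"`, `"synthetic_us"`) are synthetic
stand-ins with realistic magnitudes, used for tests and simulation only.

## Temporal event-history categories

The central covariates are, per event type, mutually exclusive
categories of time since the qualifying occurrence: none, within 1 year
(a gap of exactly 1.0 year counts as "within 1 year"), 1–2, 2–3, and
more than 3 years, with a year equal to 365.25 days.  Two clocks are
used deliberately:

* **QoL clock** — time from the *last* occurrence to the QoL
  measurement day (`qol_category()`): quality of life responds most to
  recent events, and a recurrence resets the clock.
* **Cost clock** — annual periods relative to the *first* occurrence
  since randomization (`cost_category()`): costs are attributed to
  disease onset, and recurrences do not move the clock.

Events on the measurement day itself count as within-1-year.  An event
is *fatal* when death occurs in the same annual period
(`classify_fatal()`).  Events between a participant's final QoL
measurement and the administrative end of follow-up are excluded from
the QoL analysis (in the generator both days coincide, so the rule is
vacuous there).

## Hospital costs

Admissions with overlapping stays — including same-day readmissions —
are combined into episodes with costs summed (`merge_overlapping()`).
Each episode is assigned wholly to the annual period containing its
admission day (costs are per admission; no pro-rating across period
boundaries), inflated to the target price year and, for the US Medicare
convention, given a 20% professional-fee uplift (`annualize()`).  Price
factors are configuration inputs, never hard-coded.  Casemix grouping
(HRG/DRG) is upstream of this package: episodes arrive with unit costs.

A participant's final partial year of administrative follow-up is kept
as a shorter exposure period.  Such partial years are *excluded from
the cost regressions* (they are not annual observations) but retained in
descriptive person-year summaries; a death year, by contrast, is treated
as a full annual observation, because terminal admissions concentrate
there and the published fatal-event cost estimates require them.  This
resolves the open question of how partial years enter the regressions;
an exposure offset was considered and rejected because the generating
model scales only administratively censored periods.

## The two models

**Quality of life.**  Final-visit utility is modelled by OLS
(`qol_lm()`) on baseline utility (centred at 0.84, the cohort mean at
randomization), age (centred at 67), sex, covariate blocks, and the
QoL-clock categories.  Factor levels are coded so the intercept is the
expected utility of the reference patient: a man aged 67 with prior MI
only, never drinker and never smoker, SBP < 125 mm Hg, BMI < 25, eGFR
>= 60, UACR < 3 and no new events.  Participants who died before the
final measurement or did not provide one are excluded, with counts
logged.  One row per participant justifies classical OLS standard
errors by default; HC1 robust errors are available behind
`robust = TRUE`.

**Costs.**  Annual cost is modelled in two parts (`two_part_glm()`):
a logistic model for incurring any cost, and an identity-link gamma GLM
for its magnitude conditional on any cost.  Urgent and nonurgent
coronary revascularisations and heart-failure admissions always happen
in hospital, so their occurrence periods are excluded from part-1
estimation and their predicted probability of cost is fixed at 1; the
event-year level of those types therefore never appears in part 1.
Standard errors on both parts are cluster-robust by participant
(`sandwich::vcovCL`; an internal equivalent handles designs with
aliased columns).  Identity-link gamma IRLS can step outside the
positive-mean region, so fitting falls back to a step-halving damped
IRLS started from a Gaussian fit; the same routine, warm-started,
powers the bootstrap refits.

**Specification choice.**  `compare_specifications()` fits one- and
two-part candidates over Gaussian/Poisson/gamma families and
identity/log links and reports a modified Park test (OLS of log squared
residuals on log fitted values; slope near 0, 1, 2 points to constant,
proportional, or squared-mean variance), a Pregibon-style link test,
AIC/BIC, RMSE and MAE.  Ranking is lexicographic — admissibility by the
two tests, then RMSE — which selects the two-part identity-link gamma
model on data generated under it.

**Covariate selection.**  `select_covariates()` performs backward
elimination of whole covariate blocks (Wald tests at the 1% level;
cluster-robust for the cost model, classical for QoL; a block is kept if
significant in either part of the two-part model) followed by a single
forward re-check of dropped blocks, with age and sex (and the
baseline-utility adjustment) always retained.  Backward-then-forward
ordering is a convention; the sources for this design name both
directions without sequencing them.

**Category merging.**  `merge_temporal_categories()` sweeps each event
type from the most distant pair of adjacent categories towards the
event year, combining a pair whenever the equality F/Wald test does not
reject at 1% and refitting before the next step; the sweep stops at the
first significant difference, and the event-year category never merges
into "no event".  For the two-part model the test uses the
cost-magnitude part with cluster-robust covariance.  A full collapse is
labelled "any" (any history), as for incident diabetes.

**Interactions.**  `add_interactions()` screens every pair of modelled
event types whose same-period event-year co-occurrences exceed 5% of
the pair's combined contributing event-years, tests the co-occurrence
indicator at 1%, and retains significant terms — in the cost-magnitude
part only, since the co-occurrence periods of admission-certain types
are excluded from part 1 by construction.

## Incremental costs by recycled prediction

`recycled_prediction()` predicts expected cost for every analysis row
twice — once with the scenario categories switched on, once with them at
"no event", all else held fixed — and averages the difference.  Expected
cost is $\hat p \times \hat\mu$; switching *on* an event-year of an
admission-certain type forces $\hat p = 1$, switching it *off* restores
the modelled probability.  The reference scenario resets only the
target event's categories, leaving other events as observed, so the
estimate is the *additional* cost of that event.  Categories merged
away are resolved through the merged-category map.

Uncertainty comes from a cluster bootstrap (`cluster_bootstrap()`,
`incremental_costs()`): participants are resampled with replacement
with all their annual periods, both parts are refitted under the fixed
final specification, and percentile 2.5/97.5 intervals are taken over
`B` resamples (1000 in a headline analysis; tests use reduced `B`).
Percentile intervals are used because the published intervals do not
name a bootstrap flavour.  Resamples without enough positive costs are
redrawn and counted.

## The synthetic cohort generator

`generate_cohort()` draws a complete dataset bundle: baseline
covariates from published marginal frequencies (n = 21 820, 14.3%
female, mean age 67.1, 62.6% prior MI only, ...), uniform 4.2–5.0-year
follow-up (≈97 000 person-years), ten event processes with published
cumulative incidences (4.5% MI, ..., 3.2% vascular and 4.4% nonvascular
death as competing terminal events), EQ-5D-5L profiles at baseline and
final visit, annual costs on both UK and US price scales, and an
episode table whose merged, annualized costs reproduce the annual
series exactly.  Points worth noting:

* **Event risk is linked to baseline utility** (multiplier
  $\exp\{3(0.84-b)\}$, normalised to preserve marginal incidences).
  This "frailty" creates the confounding that makes the
  no-baseline-adjustment scenario produce larger decrement estimates,
  as a real cohort does.  About 49% of first MIs carry a same-day
  urgent revascularisation, generating the co-occurrence structure the
  interaction rule needs.
* **The final-utility noise keeps OLS unbiased despite the ceiling.**
  Final utility is a mixture of a full-health point mass (probability
  rising with the linear predictor) and a beta draw on [0, 0.97], with
  the non-full mean chosen so that E[u | X] *equals the linear
  predictor exactly*.  A naive Gaussian draw censored at 1 would
  attenuate event decrements by roughly a fifth and the generating
  values could not be recovered.  Mixture parameters (mid 0.87, scale
  0.06, precision 4) give ≈32.7% full health, mean ≈0.81 and SD ≈0.20
  at the final visit.
* **Cost draws** follow the two-part generating model with gamma shape
  0.5 (heavy right skew: mean £607/person-year with SD ≈ £2300,
  matching the published mean/SD pattern).  Generating event effects
  are calibrated so the analytic recycled-prediction increments on the
  design equal the published headline estimates (£5830 for the year of
  noncoronary revascularisation; $24 722 for MI with same-year urgent
  CRV, via a positive interaction of 10 370 on the US scale); the
  part-1 intercept (−1.652) puts any-cost person-years at 20%.
  `true_increment()` exposes the analytic increments for oracle tests.
* **Limitations.**  Covariates are drawn independently of each other
  and of baseline utility; events of different types (except the
  MI/urgent-CRV link and the death mechanics) are independent; costs
  share one admission process across price scales with perfectly
  rank-correlated magnitudes.  Passing recovery tests therefore shows
  estimator correctness under the assumed structure, not robustness to
  real-data features such as correlated comorbidity, informative
  missingness, or within-year cost timing.
* The published baseline table's eGFR rows place 85.7% of participants
  below 45 mL/min per 1.73 m² — almost certainly a transposition of the
  ≥60 row, implausible for this population — but the generator follows
  the printed categories; the reference level remains ≥60, so the
  choice only changes how many participants sit at the reference.

## Numerical choices and degenerate inputs

Year length is 365.25 days with half-open bins; the 1-year boundary is
inclusive.  Identity-link gamma fits guard every IRLS step to keep
fitted means positive (step-halving, deviance-monotone, relative
tolerance 1e-10 for estimation and 1e-7 inside bootstrap refits).
Factor terms that are constant in an estimation subsample are pruned
from that part (their effects are zero by construction); factor levels
absent from a part's estimation sample count as the reference level in
prediction; coefficients aliased by collinearity are set to zero with a
warning and the cluster covariance is computed over the estimable
columns.  Ties in nearest-profile inversion break to the
lexicographically smallest profile.  Empty episode tables, zero event
rates and a `-Inf` any-cost intercept are valid degenerate inputs.

## Problem sizes used in the tests

The test suite checks QoL parameter recovery at the full study size
(20 replicates of n = 21 820) and cost-increment bootstrap coverage on
reduced cohorts (20 replicates of n = 3000 with B = 200) — below that
size the percentile intervals of the heavily skewed gamma increments
visibly under-cover, so n = 3000 is the smallest scale at which the
coverage property is meaningfully testable; the bootstrap-coverage
property test uses 50 replicates of a 150-participant single-event
design, and the specification-search check runs at n = 10 000, where
the identity/log distinction has appreciable power.  The
acceptance script averages the estimators over 10 (QoL) and 5 (cost)
independently generated full-size cohorts to report stable quantities.

## Scenario analyses

`run_pipeline()` drives the end-to-end analysis from a single
configuration: simulate or load a cohort bundle, score profiles, build
both event-history clocks, reconstruct annual costs from episodes under
the configured costing convention, fit both models (optionally with
selection, merging and interaction screening), and report decrement and
incremental-cost tables with figures and a manifest (seed, config hash,
versions).  Scenario switches reproduce the published sensitivity
analyses: region subsets (UK participants for the UK perspective, North
American for the US), omission of the baseline-utility adjustment, and
an alternate tariff.
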