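---
title: "Textbook process: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Textbook process: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpaudit)
```

## The composite indicator

`tpaudit` scores an all-or-none composite of four in-hospital process
indicators for operated hip-fracture patients aged 70 and older: assessment
of malnutrition, surgery within 24 hours of emergency-department arrival,
orthogeriatric co-management during admission, and operation by an
orthopaedic-trauma certified surgeon. The composite — *textbook process*
(TP) — is met only when all four are met; a missing value on any indicator
places the patient in the non-TP group. This deliberately conservative rule
means observed TP rates *under*estimate true compliance in proportion to
indicator missingness; `tp_bookkeeping()` therefore always reports the
partition *textbook / failed-only / missing-involved*, which sums to n by
construction.

Three of the indicators are recorded tri-states in the registry. The fourth
is derived: surgery within 24 h is met iff the elapsed time from
emergency-department arrival to start of surgery is ≤ 24.0 h. Two
conventions are ours to fix, and both are configurable:

* **Elapsed hours, inclusive boundary.** Some national indicator sets use a
  "within one calendar day" rule; we read "within 24 h" literally as
  elapsed time, with 24.0 h itself counting as met
  (`tts_indicator_cutoff_hours`).
* **Funnel order.** The cumulative compliance funnel (patients surviving
  indicator 1, 1–2, 1–2–3, …) needs an indicator order; the default is
  malnutrition → surgery-within-24h → orthogeriatric → certified surgeon.
  Only the intermediate bars depend on it — the final bar equals the TP
  count under every permutation, which the test suite asserts over several
  orders.

## Registry cleaning and eligibility

Registries carry data-entry errors. Two derived intervals are capped: a
time to surgery beyond 336 h (2 weeks) and a total stay beyond 365 days are
coded missing (timestamps retained, the record flagged), making the derived
24 h indicator missing rather than failed. Eligibility then requires age ≥
70 at surgery, surgery within the configured window (2018 by default), no
pathologic or periprosthetic fracture, and presence of the mandatory
minimum (age, arrival and surgery timestamps). A record failing several
rules is tallied once under the first failing rule in the fixed order
*age, window, pathologic, periprosthetic, mandatory* — the source audit does
not state its convention, so we chose one that makes tallies deterministic
and documented it. A missing age or surgery date is tallied under
*mandatory*, because the age and window rules cannot be assessed for it.

Timestamps are ISO-8601 local clock times; no timezone arithmetic is
applied, since registry extracts carry no zone information.

## Case-mix adjusted hospital benchmarking

Hospitals differ in case-mix, so raw TP rates are not comparable. The
benchmarking chain is:

1. **Screening.** Each case-mix candidate (age, sex, ASA grade, dementia,
   Katz-6 ADL, living situation, fracture type, treatment) is compared
   between TP and non-TP patients with its declared test: pooled-variance
   independent-samples t-test for age, Mann-Whitney U for Katz-6 ADL,
   Pearson chi-square *without* continuity correction for categoricals.
   Test assignment is declared per variable rather than decided by a
   normality test, so screening is deterministic. Variables with
   p < 0.10 (`screening_alpha`) are selected.
2. **Expected-compliance model.** A maximum-likelihood logistic regression
   of TP on the selected variables (intercept-only if none), with
   treatment coding and documented reference levels (female, ASA 1–2, no
   dementia, independent living, osteosynthesis). Age and Katz-6 ADL enter
   as continuous per-unit terms; ASA as a 1–2 vs 3–4 binary.
3. **Indirect standardization.** Hospital *h*'s expected count is
   `E_h = Σ p̂_i` over its patients; the O/E ratio is judged against the
   O = E control limits `((√E ± z/2))² / E` with z = 1.96. The interval
   narrows as `1/√E`, and classification is equivalent to asking whether
   the observed *count* falls outside `(√E ± z/2)²`. Boundaries are
   inclusive to "as expected".

Two numerical choices deserve emphasis:

* **Prediction set.** By default E is summed over the model's fitting set
  (complete cases under the missing rule below), and the observed count
  entering O/E is taken over the *same* patients. Counting O over all
  patients while summing E over complete cases would bias every O/E ratio
  upward by the missing-covariate fraction and destroy the calibration of
  the O = E interval; with matched sets, the logistic score equation
  guarantees ΣO = ΣE exactly whenever the model carries an intercept (the
  test suite asserts this to 1e-6). Published benchmark tables of this
  design do not always reconcile — the worked hospital table this package
  is tested against has ΣE ≈ 780 against ΣO = 753 — and no reconciliation
  is forced here; `expected_prediction = "all_imputed"` switches to
  predicting every scored patient with mode/median-imputed covariates.
* **Rounding.** Ratios and bounds are computed from unrounded
  intermediates and rounded half-away-from-zero only for reporting
  (`benchmark_table()`), at 2 decimals by default. On printed two-decimal
  inputs a ratio can tie with a bound (e.g. O/E 0.8568 against a lower
  bound 0.8609, both printing as 0.86); classification always uses the
  unrounded values.

## Missing-data rules in tests and models

For every test or model variable: if the variable's missing fraction is
below 5% (`missing_category_threshold`), patients missing on it are
excluded from that variable's test, and listwise from models containing
it; at or above 5%, "missing" is kept as an explicit level for
categoricals. The cognitive-status field keeps a recorded "unknown" level
distinct from missing in the data model and baseline table, but "unknown"
is pooled with missing for testing and modelling, so dementia enters models
as a yes/no binary.

## Outcome-association analysis

For in-hospital complications (any of the ten registry subtypes) and
prolonged stay, patients with a missing outcome are excluded and counted.
All candidates plus TP, treatment and hospital are fitted univariably;
patient characteristics with univariable p < 0.10 join the multivariable
model, where TP, treatment and hospital are always kept. Wald confidence
intervals at z = 1.96 throughout — no profile likelihood — matching the
reporting style of clinical audit tables. Hospital contrasts are taken
against the fourth hospital in sorted order, mirroring the reference choice
in the audit this design follows.

*Prolonged stay* is a post-operative stay of ≥ 6.0 days — the inclusive
boundary follows the defining sentence ("6 days or more after operation")
over a conflicting table header ("> 6 days") elsewhere in the same source;
the cutoff is configurable. Median stays are descriptive on the total
(admission→discharge) interval, while the prolonged flag uses the
post-operative interval.

*Mortality* is summarized descriptively (overall, per TP group, per
hospital). A multivariable model is attempted only when events reach 10 per
planned parameter (`epv_minimum`; forced terms plus screened candidates) —
with ~3% in-hospital mortality in a ~1,400-patient cohort this yields a
descriptive-only verdict with the event deficit reported, rather than an
unstable fit.

The logistic fitter itself refuses two degenerate cases explicitly rather
than returning garbage: fewer events (or non-events) than parameters, and
perfect separation, which it detects from the drifting-estimate /
exploding-SE signature and reports with the separating term named.

## The synthetic registry generator

No patient-level data ships with (or was used to build) this package; the
generator exists so every pipeline stage is exercised end-to-end. Its
defaults describe a five-hospital cohort of 1,371 patients (307, 205, 281,
327, 251): age ~ Normal(84, 7.1²) truncated to 70–105; 69% female; 63% ASA
3–4; 23% dementia plus a 2.4% recorded-unknown level; Katz-6 ADL integers
with median 1 and IQR 0–4; 30% institutionalized; 45% prosthesis; fracture
types at the audit's published mix.

**Indicator compliance** is drawn per hospital from logistic models. Each
hospital × indicator pair has a configured *marginal* compliance
probability; configured case-mix effects (by default ASA 3–4 lowers the
log-odds of surgery within 24 h by 0.61, reproducing a ~62% vs ~52% TP
split by ASA group) shift individual patients, and the hospital intercept
is solved numerically so the configured marginal is preserved. Per-hospital
marginals were calibrated once so that observed TP rates *bracket* the
38–76% range a five-hospital audit of this design reports: the extreme
hospitals' expected rates clear the envelope by about two binomial standard
errors (H1 ≈ 34%, H2 ≈ 81% observed), rather than sitting on the boundary
where a fair coin would decide bracketing. Time to surgery is drawn from a
log-normal (median 18 h) truncated to the side of 24 h consistent with each
patient's drawn indicator status, so the derived indicator and the latent
draw never disagree.

**Outcomes** are drawn from logistic models given the *realized* TP status:
complications with TP log-odds ln(0.66), age ln(1.06)/year, ASA 3–4
ln(1.37), Katz ln(1.02)/point and hospital offsets; prolonged stay with TP
ln(1.01) (a calibrated null), strong institutionalized-living and hospital
effects; mortality at a 2.8% baseline with a −0.71 TP log-odds. Intercepts
were set by first-order calibration to overall rates of roughly 41%
(complications) and 44% (prolonged stay). Post-operative stay is sampled
conditional on the prolonged-stay draw, again so flag and interval agree.

**Missingness** is missing-completely-at-random per field at published-mix
rates (ASA 3.3%, Katz 4.8%, …). The three recorded indicator tri-states
are masked at 1.6% each, so ~4.7% of patients have at least one missing
indicator; the derived 24 h indicator is never masked directly, because for
an eligible patient it can only be missing via the 2-week cap. An optional
mode makes ASA missingness twice as likely in ASA 3–4 patients for
robustness experiments. All probabilities derived from linear predictors
are clipped to (1e-6, 1 − 1e-6); configurations that are infeasible before
clipping are rejected before any draw. One seeded RNG stream with a frozen
field-draw order makes generation byte-reproducible.

**What the generator does not emulate.** Case-mix variables are drawn
independently (published audits report only marginals, so any correlation
structure would be invention); missingness is MCAR by default; timestamps
have no seasonality or weekend effects; complication subtypes carry no
subtype-specific effects. Passing tests therefore demonstrate that the
*methods* are implemented correctly and behave as designed under known
truth — not that real registries satisfy these independence assumptions.

## Problem sizes and test design

The suite verifies closed-form arithmetic exactly; fits against an
independent brute-force likelihood maximization (grid start + simplex/BFGS
polish) to four decimals on a 12-row fixture; parameter recovery on a
20,000-patient cohort (every coefficient within ±0.1 log-odds; at this size
each hospital contrast has a sampling SD of ≈ 0.045, so the tolerance sits
near two standard errors of the hardest coefficient — tight but honest);
null calibration of the O = E interval over 100 seeded study-sized
replicates (≤ 10% of hospitals flagged, in practice ~2–4% because the
Poisson-style interval is conservative for binomial counts at p ≈ 0.55);
and nominal-coverage and power properties at reduced replicate counts
chosen to keep the default run around a quarter of a minute.

## Known limitations

* Hospital profiling uses fixed-effects indirect standardization; observed
  variation may partly reflect random variation and unmeasured case-mix. A
  multilevel (random-effects) model is the natural next step and is out of
  scope here.
* The O = E interval is an approximation that ignores estimation
  uncertainty in E.
* No multiple-testing adjustment is applied across hospitals, matching the
  audit convention the package follows.
* The composite weighs all four indicators equally; an indicator with a
  larger outcome impact counts no more than the others.
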