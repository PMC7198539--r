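---
title: "Methods: persistence, CMA7, stabilized IPTW and competing-risk effect models for brand vs generic bisphosphonate claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adherence analysis of dispensing claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpadhere)
```

This vignette is the package's account of its science: the measures it
computes, the assumptions behind them, the synthetic data-generating
process used to validate them, and the numerical conventions that make the
results exactly reproducible.

## The adherence model

Adherence to a chronic oral treatment decomposes into *initiation*
(starting), *implementation* (taking the drug according to the regimen
while on treatment) and *persistence* (continuing over time). Claims data
observe none of these directly — only dispensing events with a date and a
days-of-supply — so each component is operationalised:

**Persistence** is measured by a refill-gap rule. Scanning a patient's
consecutive dispensations, the patient is non-persistent at the first
dispensation not followed by a new one within `gap_multiplier` (default 2)
times that dispensation's days of supply. Supply is 30 days for a 1-month
package and 90 days for a 3-month package. Two refinements matter in
practice:

* *Hospitalization deduction.* In-hospital patients receive their drugs
  from the hospital, so hospitalized days inside a refill gap are deducted
  (overlapping stays merged first) before the gap is compared with the
  allowance.
* *The tail gap.* A patient whose last dispensation's allowance extends
  beyond the end of follow-up cannot be observed to violate the rule and
  is administratively censored as persistent. This makes the rule
  conservatively blind to stops occurring late in follow-up — especially
  with 3-month packages, whose 180-day allowance covers half the year.

Time to discontinuation is the last dispensing day plus its days of
supply. Death before that point censors the patient at the death date;
otherwise patients are censored at day 365.

**Implementation** is CMA7, the continuous multiple-interval measure of
medication availability version 7: the proportion of days of the
observation window covered by supply, where consumption is assumed
perfect until supply runs out, unconsumed supply at a new dispensation
carries over (uncapped), and hospitalized days count as covered while
freezing consumption of home supply. The window runs from the index date
to discontinuation, death, or day 365, whichever comes first, and CMA7 is
computed only for patients under treatment at least 6 months (183 days):
over shorter windows the index is dominated by the initial supply and
overestimates implementation. *Good implementation* is CMA7 ≥ 0.90, with
the boundary closed at the top.

**Confounding control.** Treatment assignment (brand vs generic at the
index dispensation) is modelled by logistic regression on sex, age
(continuous), low-income coverage, polypharmacy, Charlson class (0 / 1–2 /
≥3), 24-month fracture history, year of initiation (categorical),
administration frequency, prescriber specialty, and a year × frequency
interaction — the year trend is the dominant confounder wherever a
generic-substitution policy phases in during the study period. Stabilized
weights `sw = m/e` for treated and `(1−m)/(1−e)` for controls (with `m`
the empirical marginal brand share) keep the pseudo-population at its
original size; balance is reported as standardized differences, continuous
`d = (m₁−m₀)/√((s₁²+s₀²)/2)`, binary on the proportion scale, with the
conventional negligibility flag |d| ≤ 0.10. Rows with unknown prescriber
specialty are dropped from the models and counted.

**Effect models.** Discontinuation is analysed on the subdistribution
scale with death competing: the Fine–Gray risk-set expansion (patients
with a prior competing event remain in later risk sets, down-weighted by
an unweighted Kaplan–Meier estimate of the censoring distribution — the
original formulation's default), with the stabilized weight multiplying
each risk-set contribution, Breslow tie handling (ties are frequent on a
day grid), and a patient-clustered sandwich variance treating the weights
as fixed — the common IPTW convention; the alternative (bootstrap) is not
implemented. With zero competing events the procedure reduces exactly to a
weighted Cox model, which the test suite exploits as an equivalence
oracle. Good implementation is analysed by binomial regression with a log
link (the exponentiated group coefficient is a risk ratio), fitted in its
quasi-likelihood form — point estimates are identical and non-integer
weighted responses are tolerated — with an HC0 sandwich variance. Whether
the reference analysis used sandwich or model-based variance is not
stated in its report; sandwich is implemented and labelled as such.

## The synthetic data-generating process

The generator emulates the structure of a national claims extract: four
delimited tables (patients, dispensing, hospitalizations, deaths) plus a
machine-readable ground truth. Its defaults are the package's study
conditions and are not meant to be tuned per run.

* **Covariates** are drawn from fixed marginals shaped like a French
  osteoporosis new-user population (89% women, mean age ≈ 70, 70%
  polypharmacy, 5% fracture history, initiation years weighted toward the
  start of a 2009–2015 window).
* **Assignment** is logistic on those covariates with log-odds effects
  defaulting to a steep negative year trend (−0.55 per year), a strong
  monthly-dosing effect (+1.9), and weaker demographic effects; the
  intercept is calibrated by root-finding so the realized marginal brand
  share matches `brand_share` (default 0.55). Confounding of treatment
  assignment is therefore real, and balance diagnostics have something to
  repair. Covariates have *no* effect on the outcomes by default, so the
  marginal ground-truth effects below are exact; weighting then mainly
  costs variance, which the recovery tests absorb.
* **Discontinuation** is a latent per-day geometric stop time
  (`discontinuation_hazard_*`, defaults 0.0035 brand / 0.00324 generic):
  the patient collects every refill scheduled on or before the stop day.
  The day-scale hazard ratio is the parameter ratio exactly (1.080 at the
  defaults, matching the direction and size reported for the real-data
  design this emulates), and the latent 12-month continuation probability
  in the generic arm is about 31%. An earlier per-refill-cycle
  formulation was abandoned: with class-dependent cycle lengths (below)
  it couples the implementation mechanism to the persistence time scale
  and shifts both estimands. Persistence *observed through the refill-gap
  rule* runs higher than the latent continuation probability because of
  the tail-gap blindness described above; a constant hazard also cannot
  reproduce the early-discontinuation excess (median time ≈ 100 days)
  seen in real cohorts — both are properties of the rule and of the
  geometric assumption, not targets of the tests.
* **Implementation classes.** Each patient is latently *tight* (refill
  delay uniform on −3..+2 days) or *loose* (delay uniform on 25–40% of
  the current supply). A tight episode can lose at most 2 days per ≥30-day
  cycle and always lands at CMA7 ≥ 0.9375; a loose episode accumulates
  uncovered days worth ≥ 25% of each supply and lands below 0.9 for every
  episode shape (the narrower 15–25% band fails this contract for
  two-event 3-month-package episodes, which sit at ≈ 0.91). The class
  probability is `p_good_generic` (default 0.78) in the generic arm and
  `good_implementation_rr × p_good_generic` in the brand arm, so the true
  risk ratio of good implementation is the parameter (default 0.90) by
  construction. Residual contamination exists in one direction — late
  stoppers with a 3-month final package are observed persistent with an
  uncovered tail and can fall below 0.9 despite being tight — but it
  applies (approximately) equally to both arms and cancels in the ratio.
  With `implementation_classes = FALSE` all delays come from
  `refill_delay` (default discrete uniform −3..+14 days), a single-regime
  mode used for the end-to-end null checks; its +14-day maximum can never
  trigger the 2×-supply rule.
* **Hospitalizations** arrive as a Poisson process (0.2/patient-year) with
  1 + Poisson(6) day stays; they overlap refill gaps and exercise both the
  gap deduction and the CMA7 coverage extension. Patients with the latent
  fracture flag also receive a pre-index stay carrying a fracture
  diagnosis code, so the cohort builder's derived fracture-history
  covariate can be checked against the latent truth.
* **Deaths** occur with annual probability 0.004 (matching the ≈ 0.3–0.4%
  one-year mortality of the emulated cohort), uniformly over follow-up;
  dispensing stops at death.
* **Optional stressors** (off by default): `switch_rate` emits sustained
  brand↔generic or molecule switches to exercise switcher exclusion;
  `cortico_rate` and `exclusion_hosp_rate` emit pre-index corticosteroid
  reimbursements and excluded-diagnosis stays to exercise those filters.

What the generator does **not** emulate: dose-level variation (all
dispensations are at the defined daily dose), within-patient package-size
habits (package size is i.i.d. per event), seasonality, covariate effects
on outcomes (off by default, as above), informative censoring, and
real drug coding (molecule plus a brand flag stand in for CIP/ATC codes).
Passing recovery tests therefore show the estimators are correct under
the assumed structure, not that the real data satisfy it.

## Numerical conventions

* All computation runs on integer day offsets from each patient's index
  date; ISO dates are produced by adding offsets to the index date. Months
  become days as 1 month = 30 days, 3 months = 90 days for supplies, and
  `months × 30.4375` rounded down for washout/lookback windows.
* Every interval — supplies, gaps, hospital stays, CMA windows — is
  half-open `[start, end)`, which removes boundary-day double counting.
* The refill allowance is anchored at the dispensing date (the stricter
  reading of "a period greater than 2 times the duration of the previous
  supply"); `anchor = "exhaustion"` starts it at supply exhaustion
  instead. The allowance compares against the *previous* event's supply
  when package sizes alternate.
* CMA7 is computed by an interval ledger: per inter-event segment with
  `N` non-hospital days and `H` hospital days, consumption follows the
  Lindley recursion `stock ← max(stock + supply − N, 0)`, and covered
  days are `H` plus consumed supply. Because consumption within a segment
  is order-free, the ledger equals a day-by-day simulation exactly; the
  test suite asserts identity against an independent day-grid oracle on
  1,000 random episodes. Carry-over is uncapped — a cap would be an
  uncited deviation from the index's definition.
* Eligibility for the implementation analysis is `end day ≥ 183`
  (6 months at 30.5 days, fixed integer). A death between month 6 and
  discontinuation truncates the CMA window at death rather than excluding
  the patient — the window-truncation reading of "the date of death, or
  12 months".
* The median time to discontinuation includes persistent and censored
  patients valued at 365, which is the only convention under which a
  published upper quartile can sit at 365.
* Percentages print at one decimal with half-up rounding; the baseline
  table uses the Wilcoxon rank-sum test with normal approximation for
  continuous covariates and χ² without continuity correction for
  categorical ones, so every printed p-value is reproducible.
* Propensity scores are clamped to `[1e−12, 1 − 1e−12]` (a machine-
  precision guard, not a trim); separation is declared when more than 1%
  of fitted probabilities pin to 0/1 — a single saturated sparse
  interaction cell (e.g. one patient in a year × daily-frequency cell) is
  tolerated, a covariate that predicts the group outright is an error.
  Weight trimming is deliberately absent (the reference design mentions
  none); a percentile-trim could be added where positivity is poor.
* Same-day multiple dispensations at index take the group from the first
  record under a deterministic (patient, date, molecule, brand) sort,
  with a warning — reproducibility under an ambiguity the data cannot
  resolve.
* ICD-10 matching is prefix-based on dot-stripped codes ("S720" matches
  "S72.00"), because claims extracts vary in dot usage. The exclusion and
  fracture code lists are configurable inputs with study-shaped defaults,
  not hard-coded nosology.

## Validation design and problem sizes

The test suite validates each layer at sizes chosen to keep the full run
in minutes on one core while leaving Monte-Carlo error well inside the
asserted bands: exact-arithmetic checks on published cohort counts
(instant); the CMA7 ledger/day-grid identity on 1,000 random episodes;
Fine–Gray/Cox equivalence to 1e−6 on 20 weighted 200-patient instances
with no competing events; parameter recovery over 200 replicates of
n = 3,000 cohorts, asserting 95% CI coverage for the true hazard ratio and
risk ratio within three Monte-Carlo standard errors of 0.95 and the
correct effect direction in over 80% of replicates; full-covariate balance
(|d| ≤ 0.10 post-weighting) at n = 5,000; and an end-to-end null — zero
delay, zero hazard — in which every patient must be persistent with
CMA7 exactly 1.0 and both effect models must refuse the degenerate input.
The acceptance script reports a single n = 20,000 pipeline run alongside
the exact-arithmetic quantities.

## Known limitations

* The refill-gap rule cannot see stops in the last allowance window of
  follow-up; observed persistence is an overestimate of latent
  continuation, more so with 3-month packages.
* The geometric stop time has a constant hazard; real cohorts show excess
  early discontinuation, so simulated time-to-discontinuation quantiles
  are later than published ones even when 12-month persistence is matched.
* The ground-truth risk ratio is defined marginally over the latent
  classes; the analysis estimand (among 6-month persisters) coincides
  with it only because class and stop time are generated independently —
  a dependence between the two (plausible in real data) would open a gap
  between the two quantities.
* The sandwich variance treats weights as fixed, ignoring propensity
  estimation; for these designs that is mildly conservative.
* Fine–Gray censoring weights use the unweighted overall censoring
  distribution; with administrative censoring at 365 days and rare death
  this choice is near-immaterial, but it is a choice.
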