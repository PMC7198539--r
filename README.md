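# bpadhere

Medication-adherence analysis of brand versus generic oral bisphosphonates
from dispensing claims, as a tested, reusable R pipeline.

## The problem

Whether patients stay on generic bisphosphonates as well as they stay on
brand ones is a recurring pharmacoepidemiology question: generics differ in
excipients and galenic form, which has been hypothesised to worsen
tolerability and therefore adherence. Answering it from reimbursement
claims requires a chain of methods, each easy to get subtly wrong:

* **New-user cohort selection** — patients aged ≥ 50 whose first oral
  bisphosphonate dispensation follows a 24-month washout without any study
  drug, with configurable exclusion rules (long-term corticosteroids,
  pre-index hospitalizations for secondary-osteoporosis or GI diagnoses)
  and removal of patients who switch brand↔generic or change molecule
  within follow-up. Attrition is tracked at every filter.
* **Persistence** — time to discontinuation under a refill-gap rule: a
  patient is non-persistent at the first dispensation not followed by a
  refill within 2 × the days of supply of that dispensation (30 or 90
  days per package), with hospitalized days deducted from the gap. Time to
  discontinuation is the last dispensing date plus its days of supply;
  death censors.
* **Implementation** — CMA7, the continuous multiple-interval measure of
  medication availability version 7: the proportion of days of the
  persistence window covered by supply, assuming full adherence until
  supply runs out, carrying oversupply forward at each dispensation, and
  counting hospitalized days as covered while freezing home-supply
  consumption. Computed for patients persisting ≥ 6 months; CMA7 ≥ 0.90 is
  *good implementation*.
* **Confounding control** — a propensity model for brand initiation (sex,
  age, low-income status, polypharmacy, Charlson class, fracture history,
  year of initiation, administration frequency, prescriber specialty, plus
  a year × frequency interaction), stabilized inverse-probability-of-
  treatment weights `sw = P(brand)/e` (treated) and `(1−P(brand))/(1−e)`
  (control), and standardized-difference balance checks at the |d| ≤ 0.10
  convention.
* **Effect estimation** — the subdistribution hazard ratio of
  discontinuation with death as a competing risk (weighted Fine–Gray, via
  the risk-set expansion with Kaplan–Meier censoring weights, Breslow
  ties, patient-clustered robust variance) and the risk ratio of good
  implementation (weighted log-binomial regression with HC0 sandwich
  variance). Generic is the reference in both.

Because the nationwide claims source such analyses run on is not publicly
available, the package ships a **synthetic claims generator** that emulates
its structure — per-patient dispensing trajectories with 1-/3-month
packages and refill delays, confounded treatment assignment, group-specific
discontinuation, hospitalizations overlapping refill gaps, deaths — and
exports the latent ground truth (true hazard ratio, true risk ratio of good
implementation) so that every stage of the pipeline is testable by
parameter recovery.

## Worked example

```r
library(bpadhere)
res <- run_pipeline(pipeline_config(
  simulate = simulation_params(n_patients = 5000, seed = 42)))
print(res)
```

```
Persistence by group:
    group    n n_discontinued n_died median_time q1_time q3_time
1 generic 2177           1304      9         240     118     365
2   brand 2823           1723      5         234     118     365
  n_persistent_183d pct_persistent_183d n_persistent_365d pct_persistent_365d
1              1286                59.1               864                39.7
2              1642                58.2              1095                38.8

Implementation (CMA7) by group:
    group n_eligible n_good n_poor pct_good pct_poor mean_cma7    sd_cma7
1 generic       1286    962    324     74.8     25.2 0.9404391 0.09233051
2   brand       1642   1112    530     67.7     32.3 0.9259471 0.10007355

HR (brand vs generic) = 1.076 [0.974; 1.190]  (robust SE of log HR = 0.0511, n = 4976)
RR (brand vs generic) = 0.938 [0.874; 1.006]  (robust SE of log RR = 0.0359, n = 2916)
max post-weighting |standardized difference|: 0.078
```

Reading the output: 38.8% of brand and 39.7% of generic initiators are
still on first-line treatment at 12 months; among patients persisting at
least 6 months, 67.7% vs 74.8% reach CMA7 ≥ 0.90. The weighted Fine–Gray
hazard ratio of 1.076 says brand initiation carries a higher
discontinuation hazard (the generator's true value is 1.080); the weighted
log-binomial risk ratio of 0.938 says brand initiators are less likely to
implement well (true value 0.90; at n = 5,000 the confidence intervals are
wide). All post-weighting standardized differences are below the 0.10
negligibility threshold. The generator was calibrated so both effects run
in the same direction as the published real-data study this design
emulates.

Individual stages are exposed as plain functions —
`simulate_claims()`, `build_cohort()`, `build_episodes()`,
`compute_cma7()`, `detect_discontinuation()`, `estimate_weights()`,
`fit_fine_gray()`, `fit_log_binomial()` — and a thin command-line wrapper
lives at `inst/scripts/adherence-pipeline.R`.

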