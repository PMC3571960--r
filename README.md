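# clubmsm

Marginal structural models for evaluating **adherence clubs** — group-based
ART delivery for stable HIV patients — against routine clinic-based care,
from longitudinal register data.

## The problem and the model

Clubs are offered to patients who are already doing well (CD4 > 200
cells/µl, virologically suppressed, ≥ 18 months on ART), and the same
time-evolving markers predict retention and virologic outcomes. Adjusting
for covariates at a single time point cannot remove this time-varying
confounding. `clubmsm` therefore implements the standard causal pipeline on
a discrete person-month time scale:

1. **Cohort construction** — eligibility screening, person-month expansion,
   intention-to-treat club coding A(t) (once in, always in), LOCF
   covariates L(t) with a 6-month CD4 lag.
2. **Stabilized IPTW** — pooled logistic models for first club entry;
   weight at month t

   sw(t) = ∏_{s≤t} P(A_s = a_s | V, s) / P(A_s = a_s | V, L̄_s, s),

   frozen at its initiation-month value once a patient joins; stabilized
   IPCW for loss-to-follow-up censoring in the rebound analysis; percentile
   truncation and diagnostics (mean sw ≈ 1 under correct specification).
3. **MSM estimation** — weighted pooled logistic regression of the monthly
   event indicator on A(t), a restricted cubic spline in follow-up month
   (knots at the 5/25/50/75/95th percentiles) and baseline covariates;
   patient-clustered sandwich variance; exp(β̂) approximates the marginal
   hazard ratio because monthly events are rare.
4. **Descriptives** — crude rates per 1000 person-years with exact
   (Garwood) Poisson intervals, rate ratios, Table-1-style stratified
   summaries.
5. **Synthetic cohorts with known truth** — a generator with the study's
   confounding structure (healthier patients join clubs) and a
   counterfactual-simulation oracle for the true marginal hazard ratio, so
   every stage is testable without any patient data.

Endpoints: combined **death / loss to follow-up**, and **virologic rebound**
(first VL > 400 copies/ml, entry-suppressed patients, LTF treated as
censoring with IPCW).

## Worked example

```r
library(clubmsm)

co  <- simulate_cohort(preset("confounded", n_patients = 2000), seed = 1)
pm  <- build_person_month_table(co$baseline, co$measurements, "death_ltf")
k   <- spline_knots(pm$t)
den <- fit_treatment_model(pm, knots = k)                      # full covariates
num <- fit_treatment_model(pm, blocks = "baseline", knots = k) # stabilization
w   <- combine_weights(compute_stabilized_iptw(pm, den, num))
weight_diagnostics(w$w)$mean
fit_weighted_pooled_logistic(pm, w, knots = k)
fit_unweighted_comparator(pm, knots = k)
```

prints

```
person-months: 36995  events: 312
mean stabilized weight: 1.001 (sd 0.120)
IPTW-weighted pooled logistic MSM fit (baseline-adjusted)
  HR for club participation: 0.46 (95% CI 0.27-0.77)
  2000 patients, 36995 person-months, 312 events
Unweighted pooled logistic MSM fit (baseline-adjusted)
  HR for club participation: 0.45 (95% CI 0.27-0.73)
```

Read: after weighting, club participation halves the monthly hazard of
death/LTF (HR 0.46); the generator's true conditional HR is 0.43 and its
counterfactual-oracle marginal HR ≈ 0.44
(`oracle_marginal_hr(preset("confounded"), 1e5, seed = 1)`). The crude
club-vs-routine rate ratio in the same cohort is 0.34 — more extreme than
the truth, the signature of healthy-joiner confounding that the weights
remove.

Command line, end to end:

```sh
Rscript inst/cli/clubmsm.R simulate --preset confounded --n 2000 --seed 1 --out cohort/
Rscript inst/cli/clubmsm.R analyze --in cohort/ --outcome death_ltf --out report/
```

`report/` then contains the weight series and diagnostics, weighted and
unweighted fits (JSON), the weighted-vs-unweighted comparison, a
Table-1-style summary, the truncation/specification sensitivity suite and a
manifest with the seed and all parameters.

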