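---
title: "Forecasting ICU bed occupancy with random survival forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting ICU bed occupancy with random survival forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icubeds)
```

## The model

`icubeds` forecasts how many of the patients currently admitted to an
intensive-care unit will still occupy a bed on each of the next days. The
key modelling move is to treat the problem as survival analysis at the
group level rather than regression at the patient level:

* **Discharge is the event of interest.** A patient "survives" while they
  remain in the ICU; leaving the ICU alive is the event. In-ICU death is
  treated as right censoring: at the moment of death we stop observing the
  (counterfactual) time to discharge.
* **Each patient gets a survival function.** A Random Survival Forest
  (RSF) maps the patient's predictors $x$ to an ensemble cumulative hazard
  $H_e(t, x)$ — the average over $B$ bootstrap trees of the Nelson–Aalen
  estimator $N(t)=\sum_{t_l \le t} d_l / I_l$ stored in the terminal node
  that $x$ reaches ($d_l$ events and $I_l$ cases at risk at event time
  $t_l$, among the in-bag cases of that node). The survival function is
  $S(t, x) = \exp(-H_e(t, x))$, read as the probability that the patient
  still occupies a bed $t$ days after the prediction morning.
* **Occupancy is the sum of survival functions.** For a group of patients
  $x_1, \dots, x_n$, the expected occupancy is
  $\mathrm{load}_{pred}(t) = \sum_i S(t, x_i)$, evaluated on the integer
  day grid $t = 0, \dots, 10$ with day 0 the prediction morning.

Trees are grown on bootstrap samples with the log-rank splitting rule:
at each node, `mtry` candidate variables are sampled, candidate cuts are
the midpoints between consecutive distinct values within the node, and the
split maximising the absolute standardised two-sample log-rank statistic
is taken. Splitting stops when a daughter node would retain fewer than
$d_0$ unique event times (or `max_depth` is reached).

### Predictors: SOFA scores in a sliding window

The Sequential Organ Failure Assessment (SOFA) score grades six organ
systems — coagulation, renal, liver, central nervous system, respiration,
cardiovascular — each 0 (normal) to 4 (severe failure), from the worst
values of routine measurements over a 24 h window (platelet count,
creatinine and urine output, bilirubin, Glasgow coma score, PaO2/FiO2
ratio with ventilation status, arterial pressure and vasopressor doses).
`sofa_coagulation()` through `sofa_cardiovascular()` implement the exact
piecewise mappings; `score_day()` sums them into the daily total (0–24).

Each stay of 3–16 days contributes one supervised entry per morning from
day 4 to its last day: the six subscores of the three preceding days (18
features, suffix `_d3` = most recent), the days already admitted (1
feature), the remaining length of stay as target, and an event flag that
is `FALSE` when the stay ended in death. A stay of $l$ days yields
$l - 3$ entries with targets $l-3, \dots, 1$; an entry with a zero-day
remaining stay does not exist, since the last prediction morning of a
stay is the morning *before* discharge. Stays under 3 days (too little
history for the window, and dominated by uneventful recoveries) and over
16 days (the province of prolonged-stay models) are excluded.

### Comparators

* `method_rf()` — a Random Forest regression of the remaining stay
  (residual-sum-of-squares splits, mean-valued terminal nodes, ensemble =
  mean of tree predictions). It receives the observed remaining stay of
  censored entries as-is; the comparator has no censoring mechanism, which
  is part of what it is being compared *for*.
* `method_baseline()` — predicts a patient's stay by drawing a random
  training patient and using that patient's length-of-stay value
  (`pool = "patients"`, the default). A second reading, `pool =
  "entries"`, draws a random training *entry* and uses its remaining-stay
  target; see "The two baseline readings" below.

Point predictions are scored on the same footing as the survival forest
via `predict_occupancy_pointwise()`: a patient with predicted remaining
stay $L$ occupies a bed on days $0, \dots, \lceil L\rceil - 1$.

### The error measure E

`error_measure_E()` implements the group-level protocol: sample 25
entries from the test fold without replacement, predict the group's
occupancy curve, compare with the actual curve (from observed remaining
stays, where death frees the bed — the bed count is physical) by mean
absolute error over the 11 grid days 0–10, and average over 100 such
groups. E reads as the average bed-count error over the first ten days of
a 25-bed ICU. `cross_validate()` wraps this in 10-fold cross-validation
with folds grouped **by patient**, so the sliding-window entries of one
patient never straddle train and test (a leakage the by-entry literal
reading would permit; both modes are available), and compares methods
with the continuity-corrected Wilcoxon rank-sum test on the per-fold E
values (unpaired, as rank-sum implies).

## The synthetic cohort simulator

No hospital data ships with the package; `generate_cohort()` emulates the
*structure* of the clinical problem so every stage is exercisable and
testable:

* each patient draws a latent baseline severity
  $\sigma \sim N(1.2, 0.65)$;
* a daily latent state follows a mean-reverting AR(1) process
  ($\phi = 0.7$) around $\sigma$, and each organ system adds independent
  daily noise;
* raw physiology (platelets, creatinine, urine, bilirubin, GCS, PF ratio,
  ventilation, arterial pressure, vasopressors) is produced from the
  per-organ severities through monotone transforms clipped to physiologic
  ranges, so the *scoring thresholds* are exercised on realistic
  continuous values, and each channel is independently missing with
  probability 0.05 (emulating "healthy organ, not monitored"; scoring
  imputes absent channels to subscore 0);
* each morning after day 1, discharge fires with probability
  $\mathrm{logit}^{-1}(0.95 - 0.3 \cdot \mathrm{SOFA}_{yesterday})$ and
  death, independently, with probability
  $0.012 \cdot \max(0, \mathrm{SOFA}_{yesterday} - 10)$; death wins a
  tie, and stays reaching 60 days are truncated as discharges.

The defaults were chosen once, for face realism of a general ICU: the
filtered (3–16-day) sub-cohort has a median stay of about 5 days and
roughly 3 entries per patient, in-ICU death is a clear minority outcome
(roughly one patient in ten), a large short-stay group is generated and
then excluded by the filters (as in real ICU extractions), and recent
SOFA carries a strong positive association with the remaining stay of
survivors. Per-patient RNG sub-streams derived from `(seed, patient
index)` make cohorts reproducible and stable under reordering.

What the simulator does **not** emulate: correlated multi-organ failure
syndromes (organ severities share one latent factor but have no disease
structure), measurement error patterns, readmissions, inter-ward
transfers, arrival processes, or any calibration to a real hospital's
distributions. Passing tests on synthetic cohorts therefore demonstrate
that the pipeline's *mechanics and directional behaviour* are right, not
that any particular error level would be attained on real data.

## The two baseline readings, and a group-level bias

The resampling baseline is described at the patient level: sample a
random patient, use their length-of-stay value. Because the evaluation
protocol samples *entries*, a second reading suggests itself: draw a
random entry's remaining-stay target. These differ sharply:

* the **entry** pool draws from the same distribution as the evaluation
  groups' actual remaining stays, so its expected occupancy curve is
  essentially unbiased — only group-sampling noise separates it from the
  truth;
* the **patient** pool draws total stays (3–16 days) as predictions of
  remaining stays, a systematic over-prediction.

The survival forest's expected curve, meanwhile, carries a structural
upward bias at these time scales, visible in the test suite: with daily
discharge hazards around 0.2–0.3, $\exp(-\sum d_l/I_l)$ exceeds the
product-limit form $\prod (1 - d_l/I_l)$ noticeably, and beds freed by
death are invisible to a model that treats death as censoring. On
simulated cohorts the forest's predicted load therefore overshoots the
realised load in the mid-horizon, it decisively beats the patient-level
baseline (the package default, matching the baseline as originally
described), and the entry-level variant — exposed as
`method_baseline("entries")` — is the markedly stronger comparator. Users
who want a censoring-aware *point* of comparison should prefer the entry
variant; users reproducing the original three-way comparison should use
the default.

## Numerical choices

* **SOFA branch overlaps.** The printed piecewise conditions overlap;
  they are evaluated most-severe-first (4 down to 0), the only ordering
  that makes them exhaustive and exclusive, and the standard SOFA
  convention. Drug-dose intervals are half-open: dopamine $(0,5] \to 2$,
  $(5,15] \to 3$, $>15 \to 4$; epinephrine/norepinephrine $(0,0.1] \to
  3$, $>0.1 \to 4$.
* **Absent measurements** score 0 at scoring time (the clinician left a
  healthy organ unmonitored). A GCS recorded under sedation is the last
  pre-sedation value, supplied by the data source (the simulator carries
  it forward).
* **Split search.** Candidate cuts are midpoints between consecutive
  distinct in-node values — deterministic and exhaustive for these
  small-range predictors. Ties in $|$log-rank$|$ resolve to the lowest
  variable index, then the lowest cut value, making forests invariant to
  row order. The log-rank variance term uses the hypergeometric form with
  the $(I_l - d_l)/(I_l - 1)$ correction; risk sets of size 1 contribute
  nothing.
* **Stopping.** A split is admissible only if both daughters retain at
  least $d_0$ unique event times ($d_0 = 3$ by default, configurable);
  a $d_0$ above the number of event times leaves trees unsplit, which is
  also the degenerate configuration under which a single tree must — and
  does, exactly — reproduce the cohort Nelson–Aalen estimator.
* **Step functions** are right-continuous with an explicit pre-first-knot
  value (0 for a cumulative hazard, 1 for a survival function); no
  interpolation anywhere. Terminal-node hazards are evaluated on the
  global grid of training event times, so ensemble averaging is exact.
* **Survival convention.** The survival function is implemented as
  $P(T > t) = \exp(-H(t))$ — "the probability the patient is still
  admitted" — even though one printed formula renders it as $P(T < t)$;
  the surrounding text and the occupancy construction require $P(T>t)$.
* **Hyperparameter defaults** ($B = 1000$, `mtry` $= \lceil\sqrt{19}\rceil
  = 5$ for the RSF and $\lceil 19/3 \rceil = 7$ for the regression forest,
  $d_0 = 3$, `min_node_size` 5, unlimited depth) follow common forest
  practice; the source analysis reports none. All are configurable.
* **OOB error functional.** The Breiman–Cutler importance needs an error
  functional; for survival forests the package uses $1 -$ Harrell's
  concordance of the ensemble mortality (the cumulative hazard summed
  over the event-time grid), the RSF literature's default, computed by
  `survival::concordance()`; regression forests use OOB mean squared
  error. Permutation is per tree within that tree's out-of-bag cases,
  then averaged — the original formulation. Normalised scores clip
  negative raw importances to zero and rescale to sum to one.
* **Seeds.** All randomness flows from integer seeds through named
  sub-streams (`derive_seed()`), so cohorts, forests, fold assignments,
  group resampling and permutations are individually reproducible, and E
  is invariant to the row order of a test fold (entries are canonically
  ordered before sampling).

## Problem sizes

The bundled examples and tests run at deliberately modest scale, chosen
so the full suite exercises every code path at desk-top cost: unit
fixtures of tens of cases; simulated cohorts of 120–600 patients for
pipeline mechanics; one 2,000-patient cohort with 200-tree forests for
the cross-validated method comparison; and an 800-entry constructed
dataset with a 150-tree forest for importance recovery. Production-scale
settings (thousands of patients, $B = 1000$) are the documented defaults.

## Known limitations

* Treating death as censoring assumes discharge and death hazards are
  independent given the predictors; the package offers no competing-risks
  machinery, and the expected-occupancy bias discussed above is the
  practical cost.
* The expected curve is not variance-quantified: no prediction intervals
  around $\mathrm{load}_{pred}$.
* New admissions are out of scope by construction; the forecast concerns
  the current population only.
* The 19 predictors are SOFA-derived only; no demographics, diagnoses or
  admission type.

```{r example, eval = FALSE}
# end-to-end, at example scale
cohort <- generate_cohort(simulation_config(n_patients = 600, seed = 42))
data <- assemble_dataset(cohort, score_cohort(cohort))
fit <- fit_rsf(data, rsf_params(n_trees = 200, seed = 1))
predict_occupancy_rsf(fit, data[1:25, ], horizon = 10)

report <- cross_validate(
  data,
  list(method_rsf(rsf_params(n_trees = 100)), method_baseline()),
  eval_config(k_folds = 5, group_size = 25, repetitions = 50, seed = 7))
report
```
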