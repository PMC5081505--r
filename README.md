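# icubeds

Forecasting intensive-care-unit (ICU) bed occupancy from the current
patient population with Random Survival Forests.

## The problem

ICU planning hinges on how many of the currently admitted patients will
still occupy a bed one, two, ..., ten days from now. Predicting each
patient's remaining length of stay individually is notoriously hard; this
package instead treats discharge as the *event* of a survival model — with
in-ICU death acting as right censoring — and forecasts the **group**: each
patient contributes a survival function
S<sub>i</sub>(t) = P(patient i still admitted at day t), and the expected
occupancy is their sum,

```
load_pred(t) = Σ_i S_i(t),   S_i(t) = exp(−H_e(t, x_i)),
```

where H<sub>e</sub>(t, x) is the ensemble cumulative hazard of a Random
Survival Forest (RSF): the average over B bootstrap trees of the
Nelson–Aalen estimator N(t) = Σ<sub>t<sub>l</sub> ≤ t</sub>
d<sub>l</sub>/I<sub>l</sub> stored in the terminal node that x reaches.
Trees are grown with the log-rank splitting rule: each node is split on the
variable/cut-value pair (from `mtry` random candidates) maximising the
absolute standardised two-sample log-rank statistic.

Predictors are built from the Sequential Organ Failure Assessment (SOFA)
score — six organ-system subscores (coagulation, renal, liver, central
nervous system, respiration, cardiovascular), each graded 0–4 from daily
clinical measurements. Every prediction morning from day 4 of a stay
onward yields one dataset entry: the 6 subscores of the previous 3 days
(18 features) plus the days already admitted (1 feature) — 19 predictors —
with the remaining length of stay as a right-censored target. Stays
shorter than 3 or longer than 16 days are excluded.

The package also implements the two comparators (a Random Forest
regression of remaining stay and a resampling baseline), the group-level
error measure E (mean absolute bed-count error over days 0–10 for random
groups of 25 entries, averaged over 100 resamples, cross-validated by
patient), Breiman–Cutler permutation variable importance, and a synthetic
ICU cohort simulator so that the whole pipeline runs without hospital
data.

## Worked example

```r
library(icubeds)
set.seed(99)

# simulate a cohort and build the supervised dataset
cohort <- generate_cohort(simulation_config(n_patients = 600, seed = 42))
data <- assemble_dataset(cohort, score_cohort(cohort))
attr(data, "provenance")$filter_log
#>          rule count
#> 1 los_under_3   308
#> 2 los_over_16    22
#> 3        kept   270
nrow(data)
#> [1] 925

# fit the survival forest and forecast occupancy for 25 current patients
fit <- fit_rsf(data, rsf_params(n_trees = 200, seed = 1))
group <- data[sample(nrow(data), 25), ]
predict_occupancy_rsf(fit, group, horizon = 10)
#> expected occupancy over days 0..10:
#>  day   beds
#>    0 25.000
#>    1 21.227
#>    2 18.114
#>    3 15.292
#>    4 13.131
#>    5 10.736
#>    6  8.731
#>    7  7.159
#>    8  6.125
#>    9  5.430
#>   10  4.739
real_occupancy(group$remaining_los, horizon = 10)
#> actual occupancy over days 0..10:
#>  day beds
#>    0   25
#>    1   18
#>    2   14
#>    3   12
#>    4   11
#>    5    7
#>    6    5
#>    7    1
#>    8    1
#>    9    1
#>   10    0
```

Of 600 simulated stays, 270 fall in the 3–16-day modelling window and
yield 925 sliding-window entries. The forecast starts at the known 25
occupied beds on day 0 and decays as patients are expected to leave; the
actual curve is the bed count implied by the observed remaining stays of
the same 25 entries.

Cross-validated comparison against the resampling baseline (which predicts
each patient's stay by drawing a random training patient's length of
stay):

```r
report <- cross_validate(data,
                         list(method_rsf(rsf_params(n_trees = 100)),
                              method_baseline()),
                         eval_config(k_folds = 5, group_size = 25,
                                     repetitions = 50, seed = 7))
report
#> Cross-validated occupancy error E (beds), 5 folds:
#>          rsf baseline
#> median 2.291    6.602
#> mean   2.406    6.763
#>
#> Pairwise Wilcoxon rank-sum (continuity-corrected):
#>  method_a method_b p_value
#>       rsf baseline  0.0122
```

E reads as the average bed-count error over the first ten days of a
25-bed ICU: about 2.3 beds for the survival forest here, versus 6.6 for
the baseline.

A thin command-line wrapper over the same functions ships in
`inst/cli/icubeds.R` (subcommands `simulate`, `score`, `build`, `train`,
`predict`, `evaluate`, `importance`), and
`vignettes/occupancy-forecasting.Rmd` documents the model, the simulator
and every numerical choice.

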