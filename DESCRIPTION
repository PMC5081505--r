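Package: icubeds
Title: Forecasting Intensive-Care-Unit Bed Occupancy with Random Survival Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts the evolution of intensive-care-unit (ICU) bed occupancy
    from the current patient population. Daily clinical measurements are mapped
    to Sequential Organ Failure Assessment (SOFA) subscores, turned into a
    sliding-window supervised dataset with remaining length of stay as a
    right-censored target (discharge is the event of interest, in-ICU death
    censors it), and modelled with a Random Survival Forest whose per-patient
    survival functions are summed into an expected occupancy curve. Includes a
    Random Forest regression comparator, a resampling baseline, a
    cross-validated group-level error measure, Breiman-Cutler permutation
    variable importance, and a synthetic-cohort simulator so the whole pipeline
    is exercisable without hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
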