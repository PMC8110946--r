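#!/usr/bin/env Rscript
# Label-retention statistics on the simulated cohorts: depletion rates
# against the disposable-model expectation, return to quiescence, dormant
# activation, and the resting/dormant decomposition of the proliferating
# pool, each compared with agent-level ground truth.

suppressPackageStartupMessages(library(nscdyn))

ts <- read_table("results/cohort_timeseries.csv", "timeseries")
tal <- read_table("results/pulse_chase_tallies.csv", "tally")
truth <- read.csv("results/pulse_chase_truth.csv")

## depletion: observed vs disposable-model expectation (Ki67+ fraction scaling)
dep <- depletion_series(ts$age_months, ts$n_total_mean, ts$frac_active_mean)
write_table(dep, "results/depletion_rates.csv")
cat("Depletion (%/day) by interval, observed vs disposable expectation:\n")
print(dep, digits = 3)
cat("\nAfter the juvenile interval the observed depletion falls below the",
    "disposable-model expectation: proliferating NSCs increasingly escape loss.\n\n")

## per-age estimators with ground truth
rows <- lapply(sort(unique(tal$age_months)), function(a) {
  sub <- pulse_chase_tally(tal[tal$age_months == a, ])
  rtq <- return_to_quiescence_fraction(sub)
  da <- dormant_activation_fraction(sub)
  rc <- resting_contribution(sub)
  tr <- truth[truth$age_months == a, ]
  data.frame(age_months = a,
             rtq = rtq$point, rtq_lo = rtq$lower, rtq_hi = rtq$upper,
             rtq_truth = tr$truth_rtq,
             dormant_act = da$point, dormant_act_truth = tr$truth_dormant_act,
             resting_contribution = rc$resting_fraction,
             resting_contribution_truth = tr$truth_resting_origin)
})
stats <- do.call(rbind, rows)
write_table(stats, "results/label_statistics.csv")
cat("Estimators vs agent ground truth (results/label_statistics.csv):\n")
print(stats, digits = 3)
cat("\nReturn to quiescence and the resting contribution rise with age while",
    "dormant activation falls. Under these fast-shuttling conditions every",
    "estimator sits below its ground truth (Ki67 perdurance hides recent",
    "returns and resting cells re-enter the cycle within the window); the",
    "downward bias shrinks with age as quiescence deepens.\n")
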