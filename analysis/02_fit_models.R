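#!/usr/bin/env Rscript
# Fit compartment-model variants to the simulated cohort time series and
# rank them by AIC. The separate-activation model (resting cells activate
# rho-fold faster than dormant cells) should decisively beat the
# shared-rate model on data generated with rho = 29.2.

suppressPackageStartupMessages(library(nscdyn))
seed <- 20260922

ts <- read_table("results/cohort_timeseries.csv", "timeseries")
variants <- list(
  `separate-activation` = model_variant(),
  `shared-activation` = model_variant(shared_activation = TRUE),
  `separate+time-dep-self-renewal` = model_variant(time_dep_self_renewal = TRUE),
  `separate+time-dep-cycle` = model_variant(time_dep_cycle = TRUE))

fits <- lapply(seq_along(variants), function(i) {
  cfg <- fit_config(n_starts = 50, n_polish = 4, seed = seed + i)
  fit_variant(ts, variants[[i]], cfg)
})
ranking <- rank_variants(fits)
write_table(ranking, "results/model_ranking.csv")

cat("Model ranking (results/model_ranking.csv):\n")
print(as.data.frame(ranking), digits = 4)

best <- fits[[which.min(vapply(fits, function(f) f$aic, numeric(1)))]]
cat("\nBest-fit parameters:\n"); print(best$params)
cat(sprintf("\nRecovered resting/dormant activation ratio rho = %.1f (generating value 29.2)\n",
            best$params$rho))
write_table(data.frame(parameter = names(unclass(best$params)),
                       value = unlist(best$params)),
            "results/best_fit_parameters.csv")
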