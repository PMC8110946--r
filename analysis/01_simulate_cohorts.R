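#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a cross-sectional cohort time
# series, pulse-chase tallies with agent-level ground truth, an H2B-GFP
# dilution-ratio dataset, and a single-cell count matrix. All downstream
# analysis scripts read only these files.

suppressPackageStartupMessages(library(nscdyn))
seed <- 20260922
dir.create("results", showWarnings = FALSE)

params <- default_parameters()
cat("Study conditions:\n"); print(params)

## cohort time series (3 mice per age, 8 at 12 months, as in the cohort design)
cfg <- simulation_config(params = params, seed = seed,
                         ages_months = c(0.5, 1, 2, 6, 12),
                         n_animals = c(3, 3, 3, 3, 8))
ts <- generate_timeseries(cfg)
write_table(ts, "results/cohort_timeseries.csv")
cat("\nCohort time series (results/cohort_timeseries.csv):\n")
print(as.data.frame(ts), digits = 4)

## pulse-chase tallies at the ages where the estimators are applied
cfg_tal <- simulation_config(params = params, seed = seed + 1,
                             ages_months = c(1, 2, 6, 12), n_animals = 3,
                             cells_per_mouse = 500)
tal <- generate_tallies(cfg_tal)
write_table(tal, "results/pulse_chase_tallies.csv")
write_table(attr(tal, "truth"), "results/pulse_chase_truth.csv")
cat("\nTally ground truth by age:\n")
print(attr(tal, "truth"), digits = 3)

## dilution ratios: juvenile-like and adult-like division mixtures
juv <- generate_dilution_dataset(c("1" = 0.64, "2" = 0.24, "3" = 0.12),
                                 n_cells = 400, noise_sigma_log = 0.08,
                                 seed = seed + 2)
adu <- generate_dilution_dataset(c("1" = 0.50, "2" = 0.22, "3" = 0.28),
                                 n_cells = 400, noise_sigma_log = 0.08,
                                 seed = seed + 3)
juv$cohort <- "juvenile"; adu$cohort <- "adult"
write_table(rbind(juv, adu), "results/dilution_ratios.csv")
cat("\nDilution datasets written (two cohorts, 400 EdU+ NSCs each).\n")

## single-cell count matrix (v3 chemistry)
m <- generate_cell_matrix(chemistry = "v3", seed = seed + 4)
write_cell_matrix(m, "results/cell_matrix")
write.csv(m$cells, "results/cell_records.csv", row.names = FALSE)
cat("\nCell matrix:", nrow(m$counts), "features x", ncol(m$counts), "cells",
    "written under results/cell_matrix/.\n")

write_provenance("results", list(script = "01_simulate_cohorts.R"), seed)
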