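#!/usr/bin/env Rscript
# Classify the synthetic single-cell matrix into dormant, resting and
# proliferating NSCs (plus QC exclusions) and audit the calls against the
# generator's truth labels.

suppressPackageStartupMessages(library(nscdyn))

rec <- read_cell_matrix("results/cell_matrix/matrix.mtx",
                        "results/cell_matrix/features.tsv",
                        "results/cell_matrix/barcodes.tsv", chemistry = "v3")
truth <- read.csv("results/cell_matrix/truth.csv")
rec$g2sm_flag <- truth$g2sm_flag   # upstream cycle-scoring flag

st <- assign_state(rec)
out <- cbind(barcode = rec$barcode, st, true_state = truth$true_state)
write_table(out, "results/cell_states.csv")

cat("State calls vs truth:\n")
print(table(called = st$state, true = truth$true_state))
cat(sprintf("\nAccuracy: %.1f%%  |  QC pass rate: %.1f%%\n",
            100 * mean(st$state == truth$true_state),
            100 * mean(st$qc == "pass")))
kept <- st$state != "excluded"
cat(sprintf("Among kept cells: %.1f%% dormant, %.1f%% resting, %.1f%% proliferating\n",
            100 * mean(st$state[kept] == "dormant"),
            100 * mean(st$state[kept] == "resting"),
            100 * mean(st$state[kept] == "proliferating")))
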