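# Single-cell QC gate, reporter call, index scoring and state assignment.

test_that("QC thresholds are strict inequalities", {
  expect_equal(qc_filter(600, 0.05), "pass")
  expect_equal(qc_filter(500, 0.05), "fail_genes")   # not "more than 500"
  expect_equal(qc_filter(501, 0.10), "fail_mito")    # not "fewer than 10%"
  expect_equal(qc_filter(501, 0.0999), "pass")
  expect_equal(qc_filter(c(600, 500), c(0.05, 0.05)),
               c("pass", "fail_genes"))
  expect_error(qc_filter(600, 1.2), "mito_fraction")
})

test_that("tdTomato call applies the read thresholds per chemistry", {
  expect_true(classify_tdtomato(0, 2, "v2"))
  expect_false(classify_tdtomato(4, 10, "v2"))   # fails intact < 4
  expect_false(classify_tdtomato(0, 1, "v2"))    # fails recombined > 1
  expect_true(classify_tdtomato(3, 2, "v2"))
  # v3 doubles both bounds
  expect_true(classify_tdtomato(7, 3, "v3"))
  expect_false(classify_tdtomato(8, 10, "v3"))
  expect_false(classify_tdtomato(0, 2, "v3"))
  # optional: doubling only the positive-evidence threshold
  expect_false(classify_tdtomato(5, 9, "v3", double_intact = FALSE))
  expect_error(classify_tdtomato(1, 2, "v5"), "chemistry")
})

test_that("index score counts detected genes and caps at 9", {
  cells <- as.data.frame(setNames(as.list(rep(0, 9)), INDEX_GENES))
  expect_equal(cycle_index_score(cells), 0L)
  cells2 <- cells; cells2$Mcm2 <- 2; cells2$Mcm5 <- 1; cells2$Pcna <- 3
  expect_equal(cycle_index_score(cells2), 3L)
  cells3 <- as.data.frame(setNames(as.list(rep(1, 9)), INDEX_GENES))
  expect_equal(cycle_index_score(cells3), 9L)
  expect_error(cycle_index_score(cells[, -1]), "missing index gene")
})

test_that("phase call applies the chemistry-doubled score threshold", {
  expect_equal(classify_phase(2, "v2"), "G1")
  expect_equal(classify_phase(1, "v2"), "quiescent")
  expect_equal(classify_phase(2, "v3"), "quiescent")
  expect_equal(classify_phase(3, "v3"), "G1")
  expect_error(classify_phase(10, "v2"), "score")
})

make_cell <- function(idx = 0, intact = 0, recombined = 0, genes = 800,
                      mito = 0.02, chem = "v2", g2sm = FALSE) {
  df <- as.data.frame(setNames(as.list(rep(0, 9)), INDEX_GENES))
  if (idx > 0) df[, seq_len(idx)] <- 1
  df$intact_reads <- intact; df$recombined_reads <- recombined
  df$genes_detected <- genes; df$mito_fraction <- mito
  df$chemistry <- chem; df$g2sm_flag <- g2sm
  df
}

test_that("state assignment follows the dormant/resting/proliferating rules", {
  # quiescent, tdTomato- -> dormant
  expect_equal(assign_state(make_cell())$state, "dormant")
  # quiescent, tdTomato+ -> resting
  expect_equal(assign_state(make_cell(idx = 1, recombined = 5))$state, "resting")
  # G2/S/M flag -> proliferating regardless of reporter
  expect_equal(assign_state(make_cell(g2sm = TRUE))$state, "proliferating")
  # G1 by index score -> proliferating
  expect_equal(assign_state(make_cell(idx = 4, recombined = 5))$state,
               "proliferating")
  # strict mode: tdTomato- G1 cells are not phase-called proliferating
  expect_equal(assign_state(make_cell(idx = 4), strict = TRUE)$state, "dormant")
  expect_equal(assign_state(make_cell(idx = 4), strict = FALSE)$state,
               "proliferating")
  # QC failure wins
  expect_equal(assign_state(make_cell(genes = 400))$state, "excluded")
  expect_equal(assign_state(make_cell(mito = 0.3))$state, "excluded")
  # missing g2sm column warns but classifies
  cell <- make_cell(); cell$g2sm_flag <- NULL
  expect_warning(st <- assign_state(cell), "g2sm_flag")
  expect_equal(st$state, "dormant")
})

test_that("v3 calls are consistent with halved v2 reads", {
  set.seed(9)
  intact <- rpois(200, 3); recombined <- rpois(200, 3)
  v3 <- classify_tdtomato(intact, recombined, "v3")
  v2_halved <- classify_tdtomato(intact / 2, recombined / 2, "v2")
  expect_true(all(!v3 | v2_halved))
})

test_that("state recovery on well-separated synthetic matrices is >= 95%", {
  for (chem in c("v2", "v3")) {
    m <- generate_cell_matrix(chemistry = chem, seed = 7)
    st <- assign_state(m$cells)
    expect_gte(mean(st$state == m$truth$true_state), 0.95)
    # cells with index score 0 are never phase-called proliferating
    zero <- st$index_score == 0 & !m$cells$g2sm_flag
    expect_false(any(st$state[zero] == "proliferating"))
  }
})

test_that("MTX round trip reproduces the per-cell records", {
  m <- generate_cell_matrix(n_dormant = 40, n_resting = 15,
                            n_proliferating = 25, seed = 3)
  dir <- file.path(tempdir(), "mtx-test")
  write_cell_matrix(m, dir)
  rec <- read_cell_matrix(file.path(dir, "matrix.mtx"),
                          file.path(dir, "features.tsv"),
                          file.path(dir, "barcodes.tsv"), chemistry = "v2")
  expect_equal(rec$genes_detected, m$cells$genes_detected)
  expect_equal(rec$intact_reads, m$cells$intact_reads)
  expect_equal(rec$recombined_reads, m$cells$recombined_reads)
  expect_equal(rec$Mcm2, m$cells$Mcm2)
  expect_equal(rec$mito_fraction, m$cells$mito_fraction, tolerance = 1e-12)
  # classification through the file path matches in-memory classification
  rec$g2sm_flag <- m$cells$g2sm_flag
  expect_equal(assign_state(rec)$state, assign_state(m$cells)$state)
})
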