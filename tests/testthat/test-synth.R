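# Synthetic-cohort generators: agent engine, time series, dilution, matrices.

test_that("agents without rates never move", {
  p <- model_parameters(alpha_d0 = 0, theta = 0, rho = 0, k_div = 0,
                        p_rest = 0, p_active = 0, p_deplete = 1,
                        d0 = 200, r0 = 0, a0 = 0)
  sim <- simulate_agents(p, model_variant(), t_max = 100, seed = 1)
  expect_equal(nrow(sim$events), 0L)
  o <- observe_agents(sim, 100, label_protocol())
  expect_true(all(o$state == "dormant"))
  expect_true(all(!o$edu))
})

test_that("the disposable limit has no resting agents and no persistence", {
  sim <- simulate_agents(disposable_params(), model_variant(),
                         t_max = 120, seed = 7)
  expect_equal(sum(sim$events$type == "div_rest"), 0L)
  expect_equal(sum(sim$events$type == "activate_r"), 0L)
  # labeled-NSC persistence after a 5-day exposure and 30-day chase
  o <- observe_agents(sim, 65, label_protocol(exposure_days = 5, chase_days = 30))
  expect_equal(sum(o$edu), 0L)
})

test_that("agent runs are pure functions of the seed", {
  s1 <- simulate_agents(default_parameters(4000), model_variant(),
                        t_max = 200, seed = 11)
  s2 <- simulate_agents(default_parameters(4000), model_variant(),
                        t_max = 200, seed = 11)
  expect_identical(s1$events, s2$events)
  s3 <- simulate_agents(default_parameters(4000), model_variant(),
                        t_max = 200, seed = 12)
  expect_false(identical(s3$events, s1$events))
})

test_that("agent observables track the ODE mean at moderate scale", {
  p <- default_parameters()
  ages <- age_to_model_time(c(1, 6))
  runs <- lapply(1:20, function(s) {
    summarize_observables(simulate_agents(p, model_variant(), 200, seed = s),
                          ages)
  })
  pred <- predict_observables(p, model_variant(), label_protocol(), ages)
  for (col in c("n_total", "frac_active", "frac_resting_labeled", "frac_labeled")) {
    m <- sapply(runs, function(r) r[[col]])
    z <- (pred[[col]] - rowMeans(m)) / (apply(m, 1, sd) / sqrt(ncol(m)))
    expect_true(all(abs(z) < 4.5), info = col)
  }
})

test_that("noise-free single-mouse time series equal the model truth", {
  cfg <- simulation_config(noise_cv = 0, cells_per_mouse = 2e6,
                           n_animals = 1, seed = 2)
  ts <- generate_timeseries(cfg)
  truth <- attr(ts, "truth")
  expect_equal(ts$n_total_mean, truth$n_total, tolerance = 1e-9)
  expect_lt(max(abs(ts$frac_active_mean - truth$frac_active)), 1e-3)
  # determinism: identical seed, identical table
  ts2 <- generate_timeseries(cfg)
  expect_identical(as.data.frame(ts), as.data.frame(ts2))
})

test_that("dilution generator obeys the halving physics", {
  d0 <- generate_dilution_dataset(c("1" = 0.3, "2" = 0.4, "3" = 0.3),
                                  n_cells = 200, noise_sigma_log = 0, seed = 1)
  expect_true(all(d0$ratio %in% c(0.5, 0.25, 0.125)))
  expect_equal(d0$ratio, 2^(-d0$divisions_true))
  expect_error(generate_dilution_dataset(c("1" = 0.5), 100), "sum to 1")
  expect_error(generate_dilution_dataset(c("1" = 1), 10), "n_cells")

  # injected neighbor triplets with SEM fraction 0.2 are all excluded
  dn <- generate_dilution_dataset(c("1" = 1), 60, 0.05, seed = 2,
                                  with_neighbors = TRUE,
                                  neighbor_sem_fraction = 0.2)
  for (i in 1:10) {
    r <- dilution_ratio(dn$cell_value[i],
                        c(dn$neighbor1[i], dn$neighbor2[i], dn$neighbor3[i]))
    expect_true(r$excluded)
    expect_equal(r$neighbor_sem_fraction, 0.2, tolerance = 1e-9)
  }
  # and with SEM fraction 0.05 they are all retained with the exact ratio
  dk <- generate_dilution_dataset(c("1" = 1), 60, 0.05, seed = 3,
                                  with_neighbors = TRUE,
                                  neighbor_sem_fraction = 0.05)
  r <- dilution_ratio(dk$cell_value[1],
                      c(dk$neighbor1[1], dk$neighbor2[1], dk$neighbor3[1]))
  expect_false(r$excluded)
  expect_equal(r$ratio, dk$ratio[1], tolerance = 1e-9)
})

test_that("cell-matrix generator honors its structural contracts", {
  # complete index dropout in G0 forces score 0 for quiescent cells
  m0 <- generate_cell_matrix(index_dropout_g0 = 1, n_proliferating = 0,
                             n_qc_low_genes = 0, n_qc_high_mito = 0, seed = 1)
  expect_true(all(cycle_index_score(m0$cells) == 0L))

  m <- generate_cell_matrix(seed = 5)
  # recombined (tdTomato-true) cells are classified positive
  td <- classify_tdtomato(m$cells$intact_reads, m$cells$recombined_reads, "v2")
  expect_gte(mean(td[m$truth$tdtomato_true]), 0.95)
  expect_lte(mean(td[!m$truth$tdtomato_true]), 0.05)

  # quiescent cells carry about half the mRNA of proliferating cells
  tot <- Matrix::colSums(m$counts)
  q <- m$truth$true_state %in% c("dormant", "resting")
  pr <- m$truth$true_state == "proliferating"
  expect_equal(mean(tot[q]) / mean(tot[pr]), 0.5, tolerance = 0.1)

  # pure function of the seed
  m2 <- generate_cell_matrix(seed = 5)
  expect_identical(as.matrix(m$counts), as.matrix(m2$counts))
})
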