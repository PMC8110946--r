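# Compartment model: activation rates, ODE solutions, observable predictions.

test_that("activation rate follows the exponential-decay hazard", {
  p <- model_parameters(alpha_d0 = 0.06, theta = 0, rho = 29.2, d0 = 1)
  expect_equal(activation_rate(p, 500, "dormant"), 0.06)

  p2 <- model_parameters(alpha_d0 = 0.06, theta = 0.012, rho = 29.2, d0 = 1)
  expect_equal(activation_rate(p2, 100, "dormant"), 0.06 * exp(-1.2),
               tolerance = 1e-12)
  # resting pool is a constant fold above dormant at any time
  for (t in c(0, 10, 250)) {
    expect_equal(activation_rate(p2, t, "resting"),
                 29.2 * activation_rate(p2, t, "dormant"))
  }
  # shared-activation variant collapses the ratio
  v <- model_variant(shared_activation = TRUE)
  expect_equal(activation_rate(p2, 50, "resting", variant = v),
               activation_rate(p2, 50, "dormant", variant = v))
  expect_error(activation_rate(p2, -1), "t must be")
})

test_that("parameter and protocol validation enforce the type invariants", {
  expect_error(model_parameters(alpha_d0 = -1, d0 = 1), "rates")
  expect_error(model_parameters(alpha_d0 = 0.1, p_rest = 0.5, p_active = 0.6,
                                p_deplete = 0.2, d0 = 1), "equal 1")
  expect_error(model_parameters(alpha_d0 = 0.1, d0 = -5), "initial sizes")
  expect_error(label_protocol(exposure_days = -1), "durations")
  expect_error(label_protocol(ki67_perdurance_hours = 80,
                              mcm2_perdurance_hours = 72), "MCM2")
  expect_error(label_protocol(s_phase_fraction_of_cycle = 0), "s_phase")
  expect_equal(n_free_params(model_variant()), 6L)
  expect_equal(n_free_params(model_variant(shared_activation = TRUE)), 5L)
  expect_equal(n_free_params(model_variant(time_dep_cycle = TRUE)), 8L)
})

test_that("ODE trajectory is constant when all rates vanish", {
  p <- model_parameters(alpha_d0 = 0, theta = 0, rho = 0, k_div = 0,
                        p_rest = 0, p_active = 0, p_deplete = 1,
                        d0 = 100, r0 = 20, a0 = 5)
  tr <- simulate_ode(p, model_variant(), seq(0, 100, by = 10))
  expect_true(all(abs(tr$d - 100) < 1e-6))
  expect_true(all(abs(tr$r - 20) < 1e-6))
  expect_true(all(abs(tr$a - 5) < 1e-6))
})

test_that("disposable limit matches the closed-form dormant solution", {
  p <- model_parameters(alpha_d0 = 0.02, theta = 0.01, rho = 0, k_div = 1,
                        p_rest = 0, p_active = 0.6, p_deplete = 0.4,
                        d0 = 1000, r0 = 0, a0 = 0)
  tg <- seq(0, 200, by = 2)
  tr <- simulate_ode(p, model_variant(), tg)
  d_analytic <- 1000 * exp(-(0.02 / 0.01) * (1 - exp(-0.01 * tg)))
  expect_lt(max(abs(tr$d - d_analytic) / d_analytic), 1e-6)
})

test_that("total pool plus cumulative depletion is conserved and non-increasing", {
  for (p in list(default_parameters(), disposable_params(), shared_params())) {
    tr <- simulate_ode(p, model_variant(), seq(0, 400, by = 5))
    n0 <- tr$n_total[1]
    expect_lt(max(abs(tr$n_total + tr$depleted_cum - n0)) / n0, 1e-6)
    expect_true(all(diff(tr$n_total) <= 1e-6 * n0))
    expect_true(all(tr$d >= 0 & tr$r >= 0 & tr$a >= 0))
  }
})

test_that("raising depletion at fixed p_active never increases the pool", {
  tg <- seq(0, 300, by = 5)
  base <- model_parameters(alpha_d0 = 0.02, theta = 0.005, rho = 10, k_div = 1,
                           p_rest = 0.3, p_active = 0.55, p_deplete = 0.15,
                           d0 = 9000, r0 = 0, a0 = 1000)
  more <- model_parameters(alpha_d0 = 0.02, theta = 0.005, rho = 10, k_div = 1,
                           p_rest = 0.15, p_active = 0.55, p_deplete = 0.30,
                           d0 = 9000, r0 = 0, a0 = 1000)
  tr1 <- simulate_ode(base, model_variant(), tg)
  tr2 <- simulate_ode(more, model_variant(), tg)
  expect_true(all(tr2$n_total <= tr1$n_total + 1e-6 * tr1$n_total[1]))
})

test_that("shared-activation variant nests the free-rho model at rho = 1", {
  p_free <- shared_params()     # rho = 1 explicitly
  tg <- seq(0, 300, by = 10)
  tr_free <- simulate_ode(p_free, model_variant(), tg)
  tr_shared <- simulate_ode(default_parameters(),
                            model_variant(shared_activation = TRUE), tg)
  # shared_activation forces rho = 1 regardless of the stored value
  p_forced <- default_parameters()
  tr_forced <- simulate_ode(p_forced, model_variant(shared_activation = TRUE), tg)
  expect_equal(tr_shared, tr_forced, tolerance = 1e-10)
  expect_equal(tr_free$n_total, tr_forced$n_total, tolerance = 1e-8)
})

test_that("predicted observables respect the labeling contracts", {
  p <- default_parameters()
  ages <- age_to_model_time(c(1, 2, 6))
  # no exposure: no label anywhere
  pr0 <- predict_observables(p, model_variant(),
                             label_protocol(exposure_days = 0), ages)
  expect_true(all(pr0$frac_labeled == 0))
  expect_true(all(pr0$frac_resting_labeled == 0))

  pr <- predict_observables(p, model_variant(), label_protocol(), ages)
  expect_true(all(pr$frac_active >= 0 & pr$frac_active <= 1))
  expect_true(all(pr$frac_labeled >= 0 & pr$frac_labeled <= 1))
  expect_true(all(pr$frac_resting_labeled <= pr$frac_labeled + 1e-12))

  # disposable limit: no resting cells, labeled or otherwise
  prd <- predict_observables(disposable_params(), model_variant(),
                             label_protocol(), ages)
  expect_true(all(prd$frac_resting_labeled < 1e-8))

  # a window reaching before model time zero yields NA label streams
  pr_na <- predict_observables(p, model_variant(), label_protocol(),
                               age_to_model_time(c(0.5, 6)))
  expect_true(is.na(pr_na$frac_resting_labeled[1]))
  expect_false(is.na(pr_na$frac_resting_labeled[2]))

  # fixed-start protocol before any exposure is an error
  expect_error(
    predict_observables(p, model_variant(),
                        label_protocol(start_age_days = 100), ages[1]),
    "before any exposure")
})
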