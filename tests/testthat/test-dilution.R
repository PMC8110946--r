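# H2B-GFP dilution: corrected fluorescence, ratios, multimodality, exact test.

test_that("corrected fluorescence subtracts the area-scaled background", {
  expect_equal(as.numeric(ctcf(1234, 50, 0)), 1234)
  expect_equal(as.numeric(ctcf(1000, 50, 2)), 900)
  v <- ctcf(100, 50, 3)
  expect_equal(as.numeric(v), -50)
  expect_true(attr(v, "negative"))
  expect_error(ctcf(100, 0, 1), "area")
})

test_that("dilution ratios and the 15% SEM exclusion behave as specified", {
  r1 <- dilution_ratio(800, c(800, 800, 800))
  expect_equal(r1$ratio, 1)
  expect_equal(r1$neighbor_sem_fraction, 0)
  expect_false(r1$excluded)

  r2 <- dilution_ratio(500, c(1000, 1000, 1000))
  expect_equal(r2$ratio, 0.5)
  expect_false(r2$excluded)

  # neighbors (1000, 400, 100): sample SD / sqrt(3) / mean ~ 0.529
  r3 <- dilution_ratio(500, c(1000, 400, 100))
  expect_equal(r3$neighbor_sem_fraction, sd(c(1000, 400, 100)) / sqrt(3) / 500,
               tolerance = 1e-12)
  expect_equal(round(r3$neighbor_sem_fraction, 3), 0.529)
  expect_true(r3$excluded)

  expect_error(dilution_ratio(500, 1000), "2-3 neighbor")
  expect_error(dilution_ratio(500, c(1, 2, 3, 4)), "2-3 neighbor")
  expect_error(dilution_ratio(-1, c(1, 2)), "> 0")

  # scale invariance: a global intensity factor changes nothing
  for (f in c(0.01, 7, 1e4)) {
    rs <- dilution_ratio(500 * f, c(1000, 400, 100) * f)
    expect_equal(rs$ratio, r3$ratio, tolerance = 1e-12)
    expect_equal(rs$excluded, r3$excluded)
  }
})

test_that("mode count estimation finds the constructed number of components", {
  # one tight component
  d1 <- generate_dilution_dataset(c("1" = 1), n_cells = 300,
                                  noise_sigma_log = 0.05, seed = 0)
  expect_equal(as.integer(estimate_mode_count(d1$ratio, seed = 0)), 1L)

  # two components a factor 2 apart
  d2 <- generate_dilution_dataset(c("1" = 0.5, "2" = 0.5), n_cells = 400,
                                  noise_sigma_log = 0.1, seed = 4)
  expect_equal(as.integer(estimate_mode_count(d2$ratio, seed = 4)), 2L)

  expect_error(estimate_mode_count(rep(0.5, 100)), "degenerate")
  expect_error(estimate_mode_count(d1$ratio[1:20]), "at least 50")
})

test_that("antimode boundaries fall at the density crossings", {
  d2 <- generate_dilution_dataset(c("1" = 0.5, "2" = 0.5), n_cells = 400,
                                  noise_sigma_log = 0.1, seed = 1)
  b <- locate_modes_antimodes(d2$ratio, 2)
  expect_length(b$boundaries, 1)
  expect_gt(b$boundaries, 0.25)
  expect_lt(b$boundaries, 0.5)
  # equal log-normal components at 0.5 and 0.25 cross at the log-midpoint
  expect_lt(abs(b$boundaries - 2^(-1.5)), 0.05)
  # boundaries sit strictly between adjacent modes
  expect_true(b$boundaries < max(b$modes) && b$boundaries > min(b$modes))

  b1 <- locate_modes_antimodes(d2$ratio, 1)
  expect_length(b1$boundaries, 0)
  expect_equal(assign_divisions(b1, c(0.6, 0.2)), c("1", "1"))
})

test_that("division assignment maps ratio bins deterministically", {
  binning <- structure(list(k = 3L, modes = c(0.5, 0.25, 0.125),
                            boundaries = c(0.35, 0.18),
                            labels = c("1", "2", ">=3"), bandwidth = 0.1),
                       class = "division_binning")
  expect_equal(assign_divisions(binning, 0.5), "1")
  expect_equal(assign_divisions(binning, 0.25), "2")
  expect_equal(assign_divisions(binning, 0.10), ">=3")
  # a ratio exactly on a boundary goes to the higher-division bin
  expect_equal(assign_divisions(binning, 0.35), "2")
  expect_equal(assign_divisions(binning, 0.18), ">=3")
  expect_error(assign_divisions(binning, NA_real_), "excluded")
})

test_that("the full pipeline recovers generated division fractions", {
  d <- generate_dilution_dataset(c("1" = 0.64, "2" = 0.24, "3" = 0.12),
                                 n_cells = 500, noise_sigma_log = 0.08, seed = 0)
  res <- count_divisions(d$ratio, seed = 0)
  expect_equal(res$k, 3L)
  truth <- c("1", "2", ">=3")[pmin(d$divisions_true, 3)]
  expect_gte(mean(as.character(res$assignments) == truth), 0.90)
  frac <- prop.table(table(res$assignments))
  expect_lt(max(abs(frac - c(0.64, 0.24, 0.12))), 0.05)
})

test_that("exact contingency test matches closed forms and fisher.test", {
  expect_equal(exact_contingency_test(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(exact_contingency_test(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-10)
  expect_equal(exact_contingency_test(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:60) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(exact_contingency_test(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
  for (i in 1:40) {
    tab <- matrix(rpois(6, 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(exact_contingency_test(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(exact_contingency_test(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  expect_error(exact_contingency_test(matrix(500L, 4, 6, byrow = TRUE)),
               "Monte Carlo")
})
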