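# Deterministic solutions of the compartment model.

param_vector <- function(params, lab_mode = 0, w0 = 0, w_eff = -1) {
  c(params$alpha_d0, params$theta, params$rho, params$k_div,
    params$p_rest, params$p_active, params$slope_rest, params$slope_cycle,
    lab_mode, w0, w_eff)
}

solve_segment <- function(y0, times, pv, func, rtol = 1e-8, atol = NULL) {
  if (is.null(atol)) atol <- 1e-8 * max(1, sum(abs(y0)))
  out <- deSolve::ode(y = y0, times = times, func = func, parms = pv,
                      dllname = "nscdyn", initfunc = "nsc_initparms",
                      rtol = rtol, atol = atol, method = "lsoda")
  m <- unclass(out)
  if (anyNA(m) || any(!is.finite(m)))
    stop("ODE solver failed (non-finite state) for parameter set: ",
         paste(sprintf("%.4g", pv), collapse = ", "))
  m
}

#' Simulate the compartment model
#'
#' Integrates the dormant/resting/active system
#' `dD/dt = -alpha_d(t) D`,
#' `dR/dt = p_rest k A - alpha_r(t) R`,
#' `dA/dt = alpha_d(t) D + alpha_r(t) R - (1 - p_active) k A`,
#' `dDep/dt = p_deplete k A`
#' with `alpha_d(t) = alpha_d0 exp(-theta t)` and `alpha_r = rho alpha_d`.
#' Because divisions are asymmetric the total pool `D + R + A` never
#' increases and `n_total(t) + depleted_cum(t)` is conserved.
#'
#' @param params an `nsc_params` object.
#' @param variant an `nsc_variant`; flags not enabled are zeroed out of
#'   the parameter set before solving.
#' @param t_grid strictly increasing times in days starting at 0.
#' @return a data frame of class `nsc_trajectory` with columns
#'   `time_days, d, r, a, depleted_cum, n_total`.
#' @export
simulate_ode <- function(params, variant = model_variant(), t_grid) {
  stopifnot(inherits(params, "nsc_params"))
  if (length(t_grid) < 2 || t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing and start at 0")
  p <- effective_params(params, variant)
  y0 <- c(D = p$d0, R = p$r0, A = p$a0, Dep = 0)
  m <- solve_segment(y0, t_grid, param_vector(p), "nsc_base_derivs")
  sizes <- m[, c("D", "R", "A", "Dep")]
  tol <- 1e-6 * max(1, sum(abs(y0)))
  if (any(sizes < -tol))
    stop("ODE solver produced negative compartment sizes")
  sizes[sizes < 0] <- 0
  traj <- data.frame(time_days = m[, "time"], d = sizes[, "D"],
                     r = sizes[, "R"], a = sizes[, "A"],
                     depleted_cum = sizes[, "Dep"])
  traj$n_total <- traj$d + traj$r + traj$a
  class(traj) <- c("nsc_trajectory", "data.frame")
  traj
}

# Solve the labeled/unlabeled duplicated system up to one observation
# time. Labeling is on inside [w0, w_eff] (NA w0 = no labeling; the
# window switch lives in the compiled right-hand side); the
# recently-rested states Z are reset at t_obs - w_ki so that Z(t_obs)
# holds the resting cells still Ki67+ by perdurance. Returns the state
# at t_obs.
solve_one_age <- function(p, base, t_obs, w0, w_eff, w_ki) {
  t_reset <- t_obs - w_ki
  labeled <- is.finite(w0)
  t_start <- max(0, min(if (labeled) w0 else Inf, t_reset))
  yb <- state_at(base, t_start)
  y <- c(D = yb[["D"]], RU = yb[["R"]], RL = 0, AU = yb[["A"]], AL = 0,
         Dep = 0, ZRU = 0, ZRL = 0)
  if (t_start >= t_obs) return(y)
  pv <- param_vector(p, lab_mode = as.numeric(labeled),
                     w0 = if (labeled) w0 else 0,
                     w_eff = if (labeled) w_eff else -1)
  if (t_reset > t_start) {
    m <- solve_segment(y, c(t_start, min(t_reset, t_obs)), pv, "nsc_label_derivs")
    y <- m[nrow(m), -1]
  }
  y[c("ZRU", "ZRL")] <- 0
  if (t_obs > max(t_start, t_reset)) {
    m <- solve_segment(y, c(max(t_start, t_reset), t_obs), pv, "nsc_label_derivs")
    y <- m[nrow(m), -1]
  }
  y
}

state_at <- function(rows, t) {
  i <- which.min(abs(rows[, "time"] - t))
  if (abs(rows[i, "time"] - t) > 1e-6)
    stop("internal: time ", t, " not on solution grid")
  rows[i, ]
}

#' Predict the measured labeling observables
#'
#' For each output age, computes the total pool size, the Ki67+ fraction
#' (active cells plus cells that returned to resting within the Ki67
#' perdurance window), the EdU+Ki67- resting fraction, and the total
#' EdU+ fraction, under the given labeling protocol. Unless the protocol
#' carries a fixed `start_age_days`, the exposure window is anchored to
#' each observation age (exposure ends `chase_days` before observation),
#' matching a cross-sectional cohort design. Label bookkeeping duplicates
#' the state space into labeled/unlabeled sub-compartments; a cell
#' becomes labeled when it completes a division whose S-phase overlapped
#' the exposure window. These predictions are the exact mean of the
#' agent-based process in [simulate_agents()].
#'
#' @param params an `nsc_params` object.
#' @param variant an `nsc_variant`.
#' @param protocol an `nsc_protocol`.
#' @param output_ages observation times in days (model time, >= 0).
#' @return a data frame of class `nsc_observables` with columns
#'   `age_days, n_total, frac_active, frac_resting_labeled, frac_labeled`.
#'   Label-derived fractions are `NA` at ages whose exposure window would
#'   begin before model time 0.
#' @export
predict_observables <- function(params, variant = model_variant(),
                                protocol = label_protocol(), output_ages) {
  stopifnot(inherits(params, "nsc_params"), inherits(protocol, "nsc_protocol"))
  if (any(output_ages < 0)) stop("output ages must be >= 0")
  p <- effective_params(params, variant)
  w_ki <- protocol$ki67_perdurance_hours / 24
  ages <- output_ages

  windows <- lapply(ages, function(t) label_window(protocol, t, p$k_div))
  if (is.finite(protocol$start_age_days)) {
    if (protocol$start_age_days < 0) stop("fixed exposure start must be >= 0")
    if (protocol$exposure_days > 0 && any(ages < protocol$start_age_days))
      stop("resting-labeled fraction requested before any exposure")
  }

  starts <- vapply(seq_along(ages), function(i) {
    w0 <- windows[[i]][1]
    valid <- protocol$exposure_days > 0 && is.finite(w0) && w0 >= 0
    max(0, min(if (valid) w0 else Inf, ages[i] - w_ki))
  }, numeric(1))
  base_times <- sort(unique(c(0, starts, ages)))
  y0 <- c(D = p$d0, R = p$r0, A = p$a0, Dep = 0)
  base <- if (length(base_times) >= 2)
    solve_segment(y0, base_times, param_vector(p), "nsc_base_derivs")
  else matrix(c(0, y0), nrow = 1, dimnames = list(NULL, c("time", names(y0))))

  res <- lapply(seq_along(ages), function(i) {
    t_obs <- ages[i]
    w0 <- windows[[i]][1]; w_eff <- windows[[i]][2]
    labeled_valid <- protocol$exposure_days > 0 && is.finite(w0) && w0 >= 0
    s <- solve_one_age(p, base, t_obs,
                       w0 = if (labeled_valid) w0 else NA_real_,
                       w_eff = if (labeled_valid) w_eff else NA_real_, w_ki)
    n_tot <- max(s[["D"]] + s[["RU"]] + s[["RL"]] + s[["AU"]] + s[["AL"]], 0)
    ki67 <- s[["AU"]] + s[["AL"]] + s[["ZRU"]] + s[["ZRL"]]
    fa <- if (n_tot > 0) min(max(ki67 / n_tot, 0), 1) else 0
    if (protocol$exposure_days == 0)
      return(data.frame(age_days = t_obs, n_total = n_tot, frac_active = fa,
                        frac_resting_labeled = 0, frac_labeled = 0))
    if (!labeled_valid)
      return(data.frame(age_days = t_obs, n_total = n_tot, frac_active = fa,
                        frac_resting_labeled = NA_real_, frac_labeled = NA_real_))
    # labeled resting cells still inside the Ki67 perdurance window count
    # as Ki67+, not as EdU+Ki67-.
    frac_rest_lab <- max(s[["RL"]] - s[["ZRL"]], 0) / max(n_tot, 1e-12)
    frac_lab <- (s[["RL"]] + s[["AL"]]) / max(n_tot, 1e-12)
    data.frame(age_days = t_obs, n_total = n_tot, frac_active = fa,
               frac_resting_labeled = min(frac_rest_lab, 1),
               frac_labeled = min(max(frac_lab, 0), 1))
  })
  out <- do.call(rbind, res)
  class(out) <- c("nsc_observables", "data.frame")
  out
}
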