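# Fitting model variants to cohort time series and ranking them by AIC.

#' Validate an observed cohort time series
#'
#' @param df data frame with columns `age_months, n_total_mean,
#'   n_total_sem, frac_active_mean, frac_active_sem, frac_resting_mean,
#'   frac_resting_sem, n_mice`.
#' @return the validated data frame, classed `nsc_series`.
#' @export
observed_series <- function(df) {
  need <- c("age_months", "n_total_mean", "n_total_sem", "frac_active_mean",
            "frac_active_sem", "frac_resting_mean", "frac_resting_sem", "n_mice")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column ", paste(miss, collapse = ", "))
  if (nrow(df) < 4) stop("at least 4 ages are required for fitting")
  if (any(diff(df$age_months) <= 0)) stop("ages must be strictly increasing")
  sems <- c(df$n_total_sem, df$frac_active_sem, df$frac_resting_sem)
  if (any(sems < 0, na.rm = TRUE)) stop("SEMs must be >= 0")
  fr <- c(df$frac_active_mean, df$frac_resting_mean)
  if (any(fr < 0 | fr > 1, na.rm = TRUE)) stop("fractions must be in [0, 1]")
  class(df) <- c("nsc_series", "data.frame")
  df
}

#' Fitting configuration
#'
#' @param weighting "inv_var" (inverse-variance, default) or "unit".
#' @param n_starts number of Latin-hypercube candidate starts.
#' @param n_polish how many of the best-scoring candidates are refined
#'   with a bounded local optimizer.
#' @param bounds named list of `c(lower, upper)` per free parameter
#'   (alpha_d0, theta, rho, p_rest, n0, frac_active0, slope_rest, k_div,
#'   slope_cycle); defaults span the biologically plausible range.
#' @param fixed named list of parameters held constant (`k_div`,
#'   `p_active`) unless a variant frees them.
#' @param protocol labeling protocol assumed for the resting stream.
#' @param rel_tol optimizer relative tolerance.
#' @param seed integer seed controlling the start design.
#' @return a list of class `nsc_fit_config`.
#' @export
fit_config <- function(weighting = c("inv_var", "unit"), n_starts = 50,
                       n_polish = 4, bounds = NULL,
                       fixed = list(k_div = 1, p_active = 0.60),
                       protocol = label_protocol(), rel_tol = 1e-8, seed = 0) {
  weighting <- match.arg(weighting)
  if (n_starts < 1) stop("n_starts must be >= 1")
  def <- list(alpha_d0 = c(1e-4, 0.5), theta = c(1e-5, 0.1), rho = c(0.5, 500),
              p_rest = c(0, NA), n0 = c(1e3, 2e5), frac_active0 = c(1e-3, 0.5),
              slope_rest = c(-0.01, 0.01), k_div = c(0.05, 5),
              slope_cycle = c(-0.01, 0.01))
  if (!is.null(bounds)) def[names(bounds)] <- bounds
  def$p_rest[2] <- if (is.na(def$p_rest[2])) 1 - fixed$p_active - 1e-6 else def$p_rest[2]
  bad <- vapply(def, function(b) !all(is.finite(b)) || b[1] > b[2], logical(1))
  if (any(bad)) stop("bounds must be finite and ordered: ",
                     paste(names(def)[bad], collapse = ", "))
  structure(list(weighting = weighting, n_starts = n_starts, n_polish = n_polish,
                 bounds = def, fixed = fixed, protocol = protocol,
                 rel_tol = rel_tol, seed = seed),
            class = "nsc_fit_config")
}

#' Weighted residual sum of squares over the three fitted streams
#'
#' The total NSC count, Ki67+ fraction and EdU+Ki67- resting fraction
#' streams are fitted jointly. With inverse-variance weighting each
#' residual is scaled by `1/SEM^2`; zero or missing SEMs receive the
#' stream's median weight so that count and fraction streams sit on a
#' comparable scale.
#'
#' @param predicted an `nsc_observables` data frame evaluated at the
#'   observed ages.
#' @param observed an `nsc_series`.
#' @param weighting "inv_var" or "unit".
#' @return list with `rss` and `n_obs` (residuals actually summed).
#' @export
residual_ss <- function(predicted, observed, weighting = c("inv_var", "unit")) {
  r <- weighted_residuals(predicted, observed, weighting)
  list(rss = sum(r^2), n_obs = length(r))
}

# Weighted residual vector across the three streams (NA pairs dropped).
weighted_residuals <- function(predicted, observed,
                               weighting = c("inv_var", "unit")) {
  weighting <- match.arg(weighting)
  t_days <- age_to_model_time(observed$age_months)
  if (nrow(predicted) != nrow(observed) ||
      any(abs(predicted$age_days - t_days) > 1e-6))
    stop("predicted ages do not match observed ages")
  streams <- list(
    list(y = observed$n_total_mean, yhat = predicted$n_total, sem = observed$n_total_sem),
    list(y = observed$frac_active_mean, yhat = predicted$frac_active, sem = observed$frac_active_sem),
    list(y = observed$frac_resting_mean, yhat = predicted$frac_resting_labeled,
         sem = observed$frac_resting_sem))
  out <- numeric(0)
  for (s in streams) {
    ok <- is.finite(s$y) & is.finite(s$yhat)
    if (!any(ok)) next
    if (weighting == "unit") {
      w <- rep(1, sum(ok))
    } else {
      sem <- s$sem[ok]
      w <- 1 / sem^2
      if (any(!is.finite(w))) {
        med <- median(w[is.finite(w)])
        if (!is.finite(med)) med <- 1
        w[!is.finite(w)] <- med
      }
    }
    out <- c(out, sqrt(w) * (s$y[ok] - s$yhat[ok]))
  }
  out
}

#' AIC for a Gaussian least-squares fit
#'
#' `AIC = n log(RSS/n) + 2k`. Adding one free parameter at identical RSS
#' increases the score by exactly 2. A perfect fit (`rss = 0`) is
#' degenerate under this form and is reported as an error.
#'
#' @param rss residual sum of squares (> 0).
#' @param n_obs number of residuals.
#' @param k number of free parameters.
#' @return numeric AIC.
#' @export
aic_score <- function(rss, n_obs, k) {
  if (n_obs <= 0) stop("n_obs must be > 0")
  if (k < 0) stop("k must be >= 0")
  if (rss <= 0) stop("rss must be > 0 (degenerate perfect fit; report separately)")
  n_obs * log(rss / n_obs) + 2 * k
}

# Free-parameter layout for a variant: names in a fixed order.
free_param_names <- function(variant) {
  nm <- c("alpha_d0", "p_rest", "n0", "frac_active0")
  if (variant$time_dep_activation) nm <- c(nm, "theta")
  if (!variant$shared_activation) nm <- c(nm, "rho")
  if (variant$time_dep_self_renewal) nm <- c(nm, "slope_rest")
  if (variant$time_dep_cycle) nm <- c(nm, "k_div", "slope_cycle")
  nm
}

# log-transform positive-rate parameters for better conditioning.
log_scaled <- c("alpha_d0", "theta", "rho", "n0", "k_div")

vec_to_params <- function(x, nm, variant, fixed) {
  v <- setNames(as.numeric(x), nm)
  v[names(v) %in% log_scaled] <- exp(v[names(v) %in% log_scaled])
  get <- function(key, default) if (key %in% nm) v[[key]] else default
  p_active <- fixed$p_active
  p_rest <- get("p_rest", 0)
  n0 <- v[["n0"]]; fa0 <- v[["frac_active0"]]
  model_parameters(
    alpha_d0 = v[["alpha_d0"]],
    theta = get("theta", 0),
    rho = if (variant$shared_activation) 1 else v[["rho"]],
    k_div = get("k_div", fixed$k_div),
    p_rest = p_rest, p_active = p_active,
    p_deplete = 1 - p_rest - p_active,
    d0 = n0 * (1 - fa0), r0 = 0, a0 = n0 * fa0,
    slope_rest = get("slope_rest", 0),
    slope_cycle = get("slope_cycle", 0))
}

#' Fit one model variant to an observed series
#'
#' Bounded multi-start local optimization of the weighted residual sum
#' of squares: `n_starts` Latin-hypercube candidates are scored, the
#' best `n_polish` are refined with `nlminb` under box bounds
#' (rate-like parameters on log scale), and the best refined solution is
#' returned. Reproducible given `config$seed`.
#'
#' @param observed an `nsc_series`.
#' @param variant an `nsc_variant`.
#' @param config an `nsc_fit_config`.
#' @return an object of class `nsc_fit`: best-fit parameters, `rss`,
#'   `n_obs`, `k`, `aic` and convergence diagnostics.
#' @export
fit_variant <- function(observed, variant, config = fit_config()) {
  observed <- observed_series(as.data.frame(observed))
  stopifnot(inherits(variant, "nsc_variant"), inherits(config, "nsc_fit_config"))
  nm <- free_param_names(variant)
  k <- n_free_params(variant)
  stopifnot(length(nm) == k)
  t_days <- age_to_model_time(observed$age_months)

  # the initial conditions are anchored near the first observation, which
  # measures them directly
  bounds <- config$bounds
  n1 <- observed$n_total_mean[1]; fa1 <- observed$frac_active_mean[1]
  if (is.finite(n1) && n1 > 0)
    bounds$n0 <- c(max(bounds$n0[1], 0.6 * n1), min(bounds$n0[2], 1.5 * n1))
  if (is.finite(fa1) && fa1 > 0)
    bounds$frac_active0 <- c(max(bounds$frac_active0[1], 0.5 * fa1),
                             min(bounds$frac_active0[2], min(2 * fa1, 0.6)))
  lower <- vapply(nm, function(s) bounds[[s]][1], numeric(1))
  upper <- vapply(nm, function(s) bounds[[s]][2], numeric(1))
  logd <- nm %in% log_scaled
  lower[logd] <- log(pmax(lower[logd], 1e-12))
  upper[logd] <- log(upper[logd])

  residuals_fn <- function(x) {
    pars <- try(vec_to_params(x, nm, variant, config$fixed), silent = TRUE)
    if (inherits(pars, "try-error")) return(rep(1e6, 3 * nrow(observed)))
    pred <- try(predict_observables(pars, variant, config$protocol, t_days),
                silent = TRUE)
    if (inherits(pred, "try-error")) return(rep(1e6, 3 * nrow(observed)))
    weighted_residuals(pred, observed, config$weighting)
  }
  objective <- function(x) sum(residuals_fn(x)^2)

  set.seed(config$seed)
  u <- lhs::randomLHS(config$n_starts, k)
  starts <- sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
  f0 <- apply(starts, 1, objective)
  ord <- order(f0)
  n_pol <- min(config$n_polish, config$n_starts)
  fits <- lapply(ord[seq_len(n_pol)], function(i) {
    f <- minpack.lm::nls.lm(
      par = starts[i, ], fn = residuals_fn, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        ftol = config$rel_tol, ptol = config$rel_tol, maxiter = 200))
    list(par = f$par, objective = f$deviance,
         convergence = as.integer(!(f$info %in% 1:4)), message = f$message)
  })
  vals <- vapply(fits, function(f) f$objective, numeric(1))
  if (all(!is.finite(vals)) || min(vals) >= 1e12)
    stop("no start converged to a finite objective; check data and bounds")
  best <- fits[[which.min(vals)]]
  pars <- vec_to_params(best$par, nm, variant, config$fixed)
  pred <- predict_observables(pars, variant, config$protocol, t_days)
  r <- residual_ss(pred, observed, config$weighting)
  structure(list(variant = variant, params = pars, rss = r$rss, n_obs = r$n_obs,
                 k = k, aic = aic_score(r$rss, r$n_obs, k),
                 convergence = best$convergence, message = best$message,
                 start_values = f0, observed = as.data.frame(observed),
                 free_names = nm),
            class = "nsc_fit")
}

#' @export
print.nsc_fit <- function(x, ...) {
  cat(sprintf("NSC model fit: k = %d, n = %d, RSS = %.6g, AIC = %.3f\n",
              x$k, x$n_obs, x$rss, x$aic))
  print(x$params)
  invisible(x)
}

#' Rank fitted variants by AIC
#'
#' @param fits list of `nsc_fit` objects fitted to the same series.
#' @return data frame of class `nsc_ranking`, ascending in AIC with
#'   `delta_aic` relative to the best fit; ties broken toward smaller `k`.
#' @export
rank_variants <- function(fits) {
  if (length(fits) < 2) {
    if (length(fits) == 1 && inherits(fits[[1]], "nsc_fit")) {
      f <- fits[[1]]
      out <- data.frame(variant = variant_label(f$variant), k = f$k,
                        rss = f$rss, aic = f$aic, delta_aic = 0)
      class(out) <- c("nsc_ranking", "data.frame")
      return(out)
    }
    stop("need a list of nsc_fit objects")
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "nsc_fit")))
  ref <- fits[[1]]$observed
  same <- vapply(fits, function(f) isTRUE(all.equal(f$observed, ref)), logical(1))
  if (!all(same)) stop("fits come from different observed series")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  k <- vapply(fits, function(f) f$k, integer(1))
  ord <- order(aic, k)
  out <- data.frame(
    variant = vapply(fits[ord], function(f) variant_label(f$variant), character(1)),
    k = k[ord],
    rss = vapply(fits[ord], function(f) f$rss, numeric(1)),
    aic = aic[ord])
  out$delta_aic <- out$aic - out$aic[1]
  class(out) <- c("nsc_ranking", "data.frame")
  out
}

variant_label <- function(variant) {
  parts <- c(
    if (variant$shared_activation) "shared-activation" else "separate-activation",
    if (variant$time_dep_activation) "time-dep-activation",
    if (variant$time_dep_self_renewal) "time-dep-self-renewal",
    if (variant$time_dep_cycle) "time-dep-cycle")
  paste(parts, collapse = "+")
}
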