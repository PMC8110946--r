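#' @keywords internal
#' @useDynLib nscdyn
#' @importFrom stats density dnbinom optim rbinom rexp rlnorm rmultinom
#'   rnbinom rnorm runif sd qnorm quantile median var nlminb setNames
#' @importFrom utils read.csv write.csv
"_PACKAGE"

#' Days per month used for age conversion
#'
#' Ages are stored in months in data files and converted to model time
#' (days since age 0.5 months, the onset of adult neurogenesis) with a
#' single constant.
#' @export
DAYS_PER_MONTH <- 30.44

#' Convert age in months to model time in days
#'
#' Model time zero corresponds to `origin_months` of age (default 0.5
#' months, when the hippocampal niche is histologically mature).
#'
#' @param age_months numeric vector of ages in months.
#' @param origin_months age corresponding to model time 0.
#' @return numeric vector of days.
#' @export
age_to_model_time <- function(age_months, origin_months = 0.5) {
  (age_months - origin_months) * DAYS_PER_MONTH
}

#' Compartment model parameters
#'
#' Rates, fate probabilities and initial sizes of the dormant (D),
#' resting (R) and active (A) NSC compartments. Activation of dormant
#' cells decays exponentially with time, `alpha_d(t) = alpha_d0 *
#' exp(-theta * t)`; resting cells activate at `rho` times the dormant
#' rate. Active cells complete divisions at rate `k_div` (1/cycle
#' duration); at completion the cell returns to resting, remains active,
#' or loses NSC identity with probabilities `p_rest`, `p_active`,
#' `p_deplete`. Divisions are asymmetric: exactly one NSC persists per
#' division, so the NSC count never increases.
#'
#' @param alpha_d0 dormant activation rate at t = 0 (per day).
#' @param theta exponential decay rate of activation (per day).
#' @param rho resting/dormant activation fold ratio (dimensionless).
#' @param k_div division-completion rate of active cells (per day).
#' @param p_rest,p_active,p_deplete fate probabilities at division
#'   completion; must sum to 1.
#' @param d0,r0,a0 initial compartment sizes (cells).
#' @param slope_rest linear time slope on `p_rest` (per day), used only
#'   by the time-dependent self-renewal variant.
#' @param slope_cycle linear time slope on `k_div` (per day^2), used only
#'   by the time-dependent cycle-duration variant.
#' @return an object of class `nsc_params`.
#' @export
model_parameters <- function(alpha_d0, theta = 0, rho = 1, k_div = 1,
                             p_rest = 0, p_active = 0, p_deplete = 1 - p_rest - p_active,
                             d0 = 0, r0 = 0, a0 = 0,
                             slope_rest = 0, slope_cycle = 0) {
  p <- list(alpha_d0 = alpha_d0, theta = theta, rho = rho, k_div = k_div,
            p_rest = p_rest, p_active = p_active, p_deplete = p_deplete,
            d0 = d0, r0 = r0, a0 = a0,
            slope_rest = slope_rest, slope_cycle = slope_cycle)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))
  if (!all(num)) stop("all parameters must be finite numeric scalars: ",
                      paste(names(p)[!num], collapse = ", "))
  rates <- c("alpha_d0", "theta", "rho", "k_div")
  if (any(unlist(p[rates]) < 0)) stop("rates must be >= 0")
  if (any(unlist(p[c("p_rest", "p_active", "p_deplete")]) < 0))
    stop("fate probabilities must be >= 0")
  if (abs(p$p_rest + p$p_active + p$p_deplete - 1) > 1e-12)
    stop("p_rest + p_active + p_deplete must equal 1 (within 1e-12)")
  if (any(unlist(p[c("d0", "r0", "a0")]) < 0)) stop("initial sizes must be >= 0")
  structure(p, class = "nsc_params")
}

#' Default (study-condition) parameter set
#'
#' Parameters of a 46,000-cell pool at onset of adult neurogenesis with a
#' 29.2-fold resting/dormant activation ratio, chosen so that the pool
#' more than halves over the first 1.5 months and then stabilizes, the
#' proliferating fraction declines from ~10%, the measured resting pool
#' stays at a few percent, and an activated NSC performs 1-3 self-renewing
#' divisions on average.
#'
#' @param n0 total initial pool size (cells).
#' @param frac_active0 initially proliferating fraction.
#' @return an `nsc_params` object.
#' @export
default_parameters <- function(n0 = 46000, frac_active0 = 0.10) {
  model_parameters(alpha_d0 = 0.018, theta = 0.009, rho = 29.2, k_div = 1,
                   p_rest = 0.24, p_active = 0.60, p_deplete = 0.16,
                   d0 = n0 * (1 - frac_active0), r0 = 0, a0 = n0 * frac_active0)
}

#' Model variant flags
#'
#' Which terms of the compartment model are free. `shared_activation`
#' forces `rho = 1` (resting and dormant cells share one activation
#' rate); `time_dep_activation` frees the exponential decay `theta`
#' (otherwise 0); `time_dep_self_renewal` and `time_dep_cycle` enable
#' linear-in-time modifiers on `p_rest` and `k_div`.
#'
#' @param shared_activation,time_dep_activation,time_dep_self_renewal,time_dep_cycle
#'   logical flags.
#' @return an object of class `nsc_variant`.
#' @export
model_variant <- function(shared_activation = FALSE, time_dep_activation = TRUE,
                          time_dep_self_renewal = FALSE, time_dep_cycle = FALSE) {
  v <- list(shared_activation = shared_activation,
            time_dep_activation = time_dep_activation,
            time_dep_self_renewal = time_dep_self_renewal,
            time_dep_cycle = time_dep_cycle)
  if (!all(vapply(v, function(x) is.logical(x) && length(x) == 1 && !is.na(x), logical(1))))
    stop("variant flags must be single logicals")
  structure(v, class = "nsc_variant")
}

#' Number of free parameters implied by a variant
#'
#' The count is a pure function of the variant flags: the baseline fit
#' frees (alpha_d0, p_rest, n0, frac_active0); `time_dep_activation`
#' adds theta, separate activation (no `shared_activation`) adds rho,
#' `time_dep_self_renewal` adds slope_rest, and `time_dep_cycle` frees
#' k_div plus its slope.
#'
#' @param variant an `nsc_variant`.
#' @return integer number of free parameters.
#' @export
n_free_params <- function(variant) {
  stopifnot(inherits(variant, "nsc_variant"))
  4L + as.integer(variant$time_dep_activation) +
    as.integer(!variant$shared_activation) +
    as.integer(variant$time_dep_self_renewal) +
    2L * as.integer(variant$time_dep_cycle)
}

# Resolve parameters against a variant: zero theta unless the variant frees
# it, force rho = 1 under shared activation, zero unused slopes.
effective_params <- function(params, variant) {
  stopifnot(inherits(params, "nsc_params"), inherits(variant, "nsc_variant"))
  p <- unclass(params)
  if (!variant$time_dep_activation) p$theta <- 0
  if (variant$shared_activation) p$rho <- 1
  if (!variant$time_dep_self_renewal) p$slope_rest <- 0
  if (!variant$time_dep_cycle) p$slope_cycle <- 0
  structure(p, class = "nsc_params")
}

#' Labeling protocol
#'
#' EdU exposure and chase design plus marker-perdurance assumptions.
#' `ki67_perdurance_hours` and `mcm2_perdurance_hours` are how long Ki67
#' and MCM2 remain detectable after a cell exits the cell cycle (MCM2
#' persists at least 72 h, roughly twice as long as Ki67).
#' `s_phase_fraction_of_cycle` is the fraction of the division cycle
#' spent in S-phase, which extends the effective labeling window past
#' the end of exposure.
#'
#' @param route "water" (continuous administration) or "pulse" (injections).
#' @param exposure_days days of EdU availability.
#' @param chase_days days between end of exposure and observation.
#' @param start_age_days optional fixed exposure start in model time; if
#'   `NA` the window is anchored to each observation age.
#' @param ki67_perdurance_hours,mcm2_perdurance_hours marker perdurance.
#' @param s_phase_fraction_of_cycle fraction of the cycle in S-phase.
#' @return an object of class `nsc_protocol`.
#' @export
label_protocol <- function(route = c("water", "pulse"), exposure_days = 14,
                           chase_days = 20 / 24, start_age_days = NA_real_,
                           ki67_perdurance_hours = 36, mcm2_perdurance_hours = 72,
                           s_phase_fraction_of_cycle = 0.5) {
  route <- match.arg(route)
  if (exposure_days < 0 || chase_days < 0) stop("durations must be >= 0")
  if (ki67_perdurance_hours < 0 || mcm2_perdurance_hours < 0)
    stop("perdurance must be >= 0")
  if (mcm2_perdurance_hours < ki67_perdurance_hours)
    stop("MCM2 perdurance must be >= Ki67 perdurance")
  if (s_phase_fraction_of_cycle <= 0 || s_phase_fraction_of_cycle > 1)
    stop("s_phase_fraction_of_cycle must be in (0, 1]")
  structure(list(route = route, exposure_days = exposure_days,
                 chase_days = chase_days, start_age_days = start_age_days,
                 ki67_perdurance_hours = ki67_perdurance_hours,
                 mcm2_perdurance_hours = mcm2_perdurance_hours,
                 s_phase_fraction_of_cycle = s_phase_fraction_of_cycle),
            class = "nsc_protocol")
}

# Effective label-acquisition window for an observation at t_obs: a division
# completing in [start, end + s_frac/k_div] had (part of) its S-phase during
# exposure. Returns c(start, end_effective, end_raw); NA start when the
# window would begin before model time 0.
label_window <- function(protocol, t_obs, k_div) {
  if (protocol$exposure_days == 0) return(c(NA_real_, NA_real_, NA_real_))
  if (is.finite(protocol$start_age_days)) {
    w0 <- protocol$start_age_days
    w1 <- w0 + protocol$exposure_days
  } else {
    w1 <- t_obs - protocol$chase_days
    w0 <- w1 - protocol$exposure_days
  }
  tail <- protocol$s_phase_fraction_of_cycle / k_div
  c(w0, min(w1 + tail, t_obs), w1)
}

#' @export
print.nsc_params <- function(x, ...) {
  cat("NSC compartment model parameters\n")
  cat(sprintf("  activation: alpha_d0 = %.4g/d, theta = %.4g/d, rho = %.4g\n",
              x$alpha_d0, x$theta, x$rho))
  cat(sprintf("  division:   k_div = %.4g/d; fates (rest, active, deplete) = (%.3g, %.3g, %.3g)\n",
              x$k_div, x$p_rest, x$p_active, x$p_deplete))
  cat(sprintf("  initial:    D = %.0f, R = %.0f, A = %.0f cells\n", x$d0, x$r0, x$a0))
  invisible(x)
}

#' @export
print.nsc_variant <- function(x, ...) {
  on <- names(x)[unlist(x)]
  cat("NSC model variant:", if (length(on)) paste(on, collapse = ", ") else "(none)",
      "| k =", n_free_params(x), "\n")
  invisible(x)
}
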