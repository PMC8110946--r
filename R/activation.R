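#' Time-dependent activation rate
#'
#' Per-cell hazard of leaving quiescence at model time `t`:
#' `alpha_d0 * exp(-theta * t)` for dormant cells, `rho` times that for
#' resting cells. Under a `shared_activation` variant the resting rate
#' equals the dormant rate.
#'
#' @param params an `nsc_params` object.
#' @param t model time in days (vectorized); must be >= 0.
#' @param pool "dormant" or "resting".
#' @param variant optional `nsc_variant` used to resolve flags.
#' @return numeric vector of rates (per day).
#' @export
activation_rate <- function(params, t, pool = c("dormant", "resting"),
                            variant = NULL) {
  pool <- match.arg(pool)
  stopifnot(inherits(params, "nsc_params"))
  if (any(t < 0)) stop("t must be >= 0")
  if (!is.null(variant)) params <- effective_params(params, variant)
  r <- params$alpha_d0 * exp(-params$theta * t)
  if (pool == "resting") r <- params$rho * r
  r
}

# Fate probabilities at a division completing at time t (time-dependent
# self-renewal clips p_rest into [0, 1 - p_active] and gives the remainder
# to depletion).
fate_probs <- function(params, t) {
  pr <- pmin(pmax(params$p_rest + params$slope_rest * t, 0), 1 - params$p_active)
  cbind(rest = pr, active = params$p_active, deplete = 1 - params$p_active - pr)
}

# Division-completion rate at time t, floored at a tiny positive value.
division_rate <- function(params, t) {
  pmax(params$k_div + params$slope_cycle * t, 1e-10)
}
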