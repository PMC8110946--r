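# Pulse-chase label-retention statistics.

#' Validate a pulse-chase tally table
#'
#' One row per mouse: EdU x Ki67 cross-counts plus the total NSC count.
#'
#' @param df data frame with columns `mouse_id, age_months, chase_hours,
#'   edu_pos_ki67_pos, edu_pos_ki67_neg, edu_neg_ki67_pos,
#'   edu_neg_ki67_neg, total_nsc`.
#' @return validated data frame, classed `nsc_tally`.
#' @export
pulse_chase_tally <- function(df) {
  need <- c("mouse_id", "age_months", "chase_hours", "edu_pos_ki67_pos",
            "edu_pos_ki67_neg", "edu_neg_ki67_pos", "edu_neg_ki67_neg",
            "total_nsc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column ", paste(miss, collapse = ", "))
  cnt <- c("edu_pos_ki67_pos", "edu_pos_ki67_neg", "edu_neg_ki67_pos",
           "edu_neg_ki67_neg", "total_nsc")
  for (cc in cnt) {
    x <- df[[cc]]
    if (any(x < 0) || any(x != round(x)))
      stop("counts must be non-negative integers: ", cc)
  }
  cross <- rowSums(df[, cnt[1:4]])
  if (any(cross > df$total_nsc + 1e-9))
    stop("cross-counts exceed total_nsc")
  class(df) <- c("nsc_tally", "data.frame")
  df
}

#' Observed NSC depletion rate between two time points
#'
#' Percentage of the pool lost per day, normalized to the pool size at
#' the earlier time point: `100 (n1 - n2) / (delta_days * n1)`. Negative
#' values (pool growth) are legal and flagged, not errors.
#'
#' @param n1 pool size at the earlier time (> 0).
#' @param n2 pool size at the later time.
#' @param delta_days interval length in days (> 0).
#' @return list of class `depletion_rate` with `rate` (%/day) and
#'   `growth` flag.
#' @export
observed_depletion_rate <- function(n1, n2, delta_days) {
  if (any(n1 <= 0)) stop("n1 must be > 0")
  if (any(delta_days <= 0)) stop("delta_days must be > 0")
  rate <- 100 * (n1 - n2) / (delta_days * n1)
  structure(list(rate = rate, growth = rate < 0), class = "depletion_rate")
}

#' Depletion rate expected under the disposable stem cell model
#'
#' The disposable model ties depletion to NSC activity, so the reference
#' depletion rate is scaled down by the relative size of the
#' proliferating pool: `d_ref * a_t / a_ref`. The proliferating-pool
#' size may be supplied as Ki67+ fractions or absolute Ki67+ counts; the
#' scaling is the ratio either way.
#'
#' @param d_ref observed depletion rate in the reference (earliest)
#'   interval, %/day, >= 0.
#' @param a_ref proliferating pool size in the reference interval (> 0).
#' @param a_t proliferating pool size at the later time.
#' @return expected depletion rate, %/day.
#' @export
expected_depletion_disposable <- function(d_ref, a_ref, a_t) {
  if (any(a_ref <= 0)) stop("a_ref must be > 0")
  if (any(d_ref < 0)) stop("d_ref must be >= 0")
  d_ref * a_t / a_ref
}

#' Depletion series for a cohort time course
#'
#' Applies [observed_depletion_rate()] to successive ages and, when
#' proliferating-pool sizes are given, the disposable-model expectation
#' anchored on the earliest interval.
#'
#' @param age_months strictly increasing ages.
#' @param n_total pool sizes at those ages.
#' @param a_proliferating optional proliferating pool sizes (fractions
#'   or counts) at those ages; the reference value is the earliest age's.
#' @return data frame with one row per interval: `age1, age2,
#'   observed_rate, growth, expected_rate`.
#' @export
depletion_series <- function(age_months, n_total, a_proliferating = NULL) {
  if (any(diff(age_months) <= 0)) stop("ages must be strictly increasing")
  m <- length(age_months)
  dd <- diff(age_months) * DAYS_PER_MONTH
  obs <- observed_depletion_rate(n_total[-m], n_total[-1], dd)
  out <- data.frame(age1 = age_months[-m], age2 = age_months[-1],
                    observed_rate = obs$rate, growth = obs$growth,
                    expected_rate = NA_real_)
  if (!is.null(a_proliferating)) {
    d_ref <- max(obs$rate[1], 0)
    out$expected_rate <- expected_depletion_disposable(
      d_ref, a_proliferating[1], a_proliferating[-m])
  }
  out
}

#' Wilson score interval for a count fraction
#'
#' @param k number of successes.
#' @param n number of trials (> 0).
#' @param level confidence level.
#' @return list of class `fraction_ci`: `k, n, point, lower, upper, level`.
#' @export
fraction_with_ci <- function(k, n, level = 0.95) {
  if (any(n <= 0)) stop("n must be > 0")
  if (any(k < 0) || any(k > n)) stop("k must be in [0, n]")
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  structure(list(k = k, n = n, point = p,
                 lower = pmax(center - half, 0), upper = pmin(center + half, 1),
                 level = level),
            class = "fraction_ci")
}

#' @export
print.fraction_ci <- function(x, ...) {
  cat(sprintf("%d / %d = %.4f  [%.4f, %.4f] (%.0f%% Wilson)\n",
              x$k, x$n, x$point, x$lower, x$upper, 100 * x$level))
  invisible(x)
}

#' Return-to-quiescence fraction
#'
#' Fraction of EdU+ NSCs that are Ki67- at the end of the chase, i.e.
#' labeled cells that exited the cell cycle. Counts are pooled across
#' mice before the fraction is formed; per-mouse fractions are attached
#' for SEM-style displays.
#'
#' @param tally an `nsc_tally` (or coercible data frame).
#' @param level confidence level for the Wilson interval.
#' @return a `fraction_ci` with a `per_mouse` data frame attached.
#' @export
return_to_quiescence_fraction <- function(tally, level = 0.95) {
  tally <- pulse_chase_tally(as.data.frame(tally))
  k <- sum(tally$edu_pos_ki67_neg)
  n <- sum(tally$edu_pos_ki67_pos) + k
  if (n == 0) stop("no EdU+ cells in tally")
  out <- fraction_with_ci(k, n, level)
  denom <- tally$edu_pos_ki67_pos + tally$edu_pos_ki67_neg
  out$per_mouse <- data.frame(mouse_id = tally$mouse_id,
                              fraction = ifelse(denom > 0,
                                                tally$edu_pos_ki67_neg / denom, NA))
  out
}

#' Dormant NSC activation fraction
#'
#' Fraction of the *total* NSC pool that is EdU-Ki67+ after prolonged
#' EdU exposure and a short chase: dormant cells that activated during
#' the chase window, normalized to the whole pool (not to the EdU- pool).
#'
#' @inheritParams return_to_quiescence_fraction
#' @return a `fraction_ci` with a `per_mouse` data frame attached.
#' @export
dormant_activation_fraction <- function(tally, level = 0.95) {
  tally <- pulse_chase_tally(as.data.frame(tally))
  n <- sum(tally$total_nsc)
  if (n == 0) stop("tally has no total NSC counts")
  k <- sum(tally$edu_neg_ki67_pos)
  out <- fraction_with_ci(k, n, level)
  out$per_mouse <- data.frame(mouse_id = tally$mouse_id,
                              fraction = ifelse(tally$total_nsc > 0,
                                                tally$edu_neg_ki67_pos / tally$total_nsc, NA))
  out
}

#' Resting/dormant decomposition of the proliferating pool
#'
#' The fraction of Ki67+ NSCs originating from the resting pool is
#' estimated as `f1 * f2`, where `f1 = P(EdU+ | Ki67+)` and
#' `f2 = P(Ki67- | EdU+)` (the probability that a labeled cell had been
#' resting at some point during the exposure). The dormant contribution
#' is the complement. The estimate assumes the probability of returning
#' to quiescence is uniform over the exposure period and identical
#' across successive divisions.
#'
#' @inheritParams return_to_quiescence_fraction
#' @return list of class `contribution_estimate`: `resting_fraction`,
#'   `dormant_fraction`, inputs `f1`, `f2`, and `assumptions`.
#' @export
resting_contribution <- function(tally) {
  tally <- pulse_chase_tally(as.data.frame(tally))
  ki67_pos <- sum(tally$edu_pos_ki67_pos) + sum(tally$edu_neg_ki67_pos)
  edu_pos <- sum(tally$edu_pos_ki67_pos) + sum(tally$edu_pos_ki67_neg)
  if (ki67_pos == 0) stop("no Ki67+ cells in tally")
  if (edu_pos == 0) stop("no EdU+ cells in tally")
  f1 <- sum(tally$edu_pos_ki67_pos) / ki67_pos
  f2 <- sum(tally$edu_pos_ki67_neg) / edu_pos
  structure(list(resting_fraction = f1 * f2, dormant_fraction = 1 - f1 * f2,
                 f1 = f1, f2 = f2,
                 assumptions = c("uniform probability of returning to quiescence over the exposure period",
                                 "equal return probability after every division")),
            class = "contribution_estimate")
}

#' @export
print.contribution_estimate <- function(x, ...) {
  cat(sprintf("Proliferating pool origin: resting %.3f, dormant %.3f (f1 = %.3f, f2 = %.3f)\n",
              x$resting_fraction, x$dormant_fraction, x$f1, x$f2))
  invisible(x)
}
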