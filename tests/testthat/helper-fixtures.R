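# Shared fixtures for the test suite. Everything is generated in code.

# Disposable-regime parameter set: no return to quiescence.
disposable_params <- function(d0 = 18000, a0 = 2000) {
  model_parameters(alpha_d0 = 0.05, theta = 0.01, rho = 0, k_div = 1,
                   p_rest = 0, p_active = 0.6, p_deplete = 0.4,
                   d0 = d0, r0 = 0, a0 = a0)
}

# Shared-activation twin of the default parameter set (rho = 1).
shared_params <- function() {
  model_parameters(alpha_d0 = 0.018, theta = 0.009, rho = 1, k_div = 1,
                   p_rest = 0.24, p_active = 0.6, p_deplete = 0.16,
                   d0 = 41400, r0 = 0, a0 = 4600)
}

# Noise-free observed series with scale-proportional SEMs, for recovery
# tests with balanced inverse-variance weights.
noise_free_series <- function(params, variant, ages = c(0.5, 1, 2, 4, 6, 9, 12),
                              rel_sem = 0.03) {
  pred <- predict_observables(params, variant, label_protocol(),
                              age_to_model_time(ages))
  observed_series(data.frame(
    age_months = ages,
    n_total_mean = pred$n_total,
    n_total_sem = rel_sem * pred$n_total,
    frac_active_mean = pred$frac_active,
    frac_active_sem = pmax(rel_sem * pred$frac_active, 1e-4),
    frac_resting_mean = pred$frac_resting_labeled,
    frac_resting_sem = pmax(rel_sem * pred$frac_resting_labeled, 1e-4),
    n_mice = 3))
}

# A small three-mouse tally with known pooled counts.
three_mouse_tally <- function() {
  pulse_chase_tally(data.frame(
    mouse_id = c("m1", "m2", "m3"), age_months = 6, chase_hours = 20,
    edu_pos_ki67_pos = c(10, 5, 3), edu_pos_ki67_neg = c(5, 10, 2),
    edu_neg_ki67_pos = c(4, 2, 1), edu_neg_ki67_neg = c(281, 283, 294),
    total_nsc = c(300, 300, 300)))
}

make_fit_cfg <- function(seed, n_starts = 40, n_polish = 3) {
  fit_config(n_starts = n_starts, n_polish = n_polish, seed = seed)
}

# Conditions where the label-retention estimators' assumptions hold:
# moderate activation ratio, modest self-renewal.
audit_params <- function() {
  model_parameters(alpha_d0 = 0.018, theta = 0.009, rho = 3, k_div = 1,
                   p_rest = 0.15, p_active = 0.6, p_deplete = 0.25,
                   d0 = 41400, r0 = 0, a0 = 4600)
}

# One agent cohort observed at a single age under the standard protocol.
pooled_observation <- function(params, age_months, seed) {
  t_obs <- age_to_model_time(age_months)
  sim <- simulate_agents(params, model_variant(), t_max = t_obs + 1, seed = seed)
  observe_agents(sim, t_obs, label_protocol())
}

# Whole-population EdU x Ki67 tally from one observation.
pooled_tally <- function(o, age_months) {
  pulse_chase_tally(data.frame(
    mouse_id = "pooled", age_months = age_months, chase_hours = 20,
    edu_pos_ki67_pos = sum(o$edu & o$ki67),
    edu_pos_ki67_neg = sum(o$edu & !o$ki67),
    edu_neg_ki67_pos = sum(!o$edu & o$ki67),
    edu_neg_ki67_neg = sum(!o$edu & !o$ki67),
    total_nsc = nrow(o)))
}
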