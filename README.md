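# nscdyn

Quantitative machinery for studying lifelong maintenance of the hippocampal
neural stem cell (NSC) pool. In juvenile mice the dentate gyrus holds
~46,000 NSCs per hemisphere and loses more than half of them within weeks;
in adults the pool stabilizes and keeps producing neurons. `nscdyn` models
this transition and implements the measurements used to dissect it, for
anyone analyzing NSC label-retention, division-counting, or single-cell
quiescence data — or simulating such experiments before running them.

The core is a compartment model of dormant (D), resting (R) and active (A)
NSCs with a decaying activation hazard:

    dD/dt = -α_D(t) D                         α_D(t) = α_D0 e^(-θt)
    dR/dt = p_rest k A - α_R(t) R             α_R(t) = ρ α_D(t)
    dA/dt = α_D(t) D + α_R(t) R - (1 - p_active) k A

Divisions are asymmetric (one NSC persists, with fates
`p_rest + p_active + p_deplete = 1`), so the pool never grows. The key
biological quantity is ρ, the fold-difference in activation rate between
resting cells (which have proliferated and returned to shallow quiescence)
and dormant cells (which never left it). Around this sit:

* **model selection** — weighted least-squares fits of model variants
  (shared vs separate activation, time-dependent self-renewal or cycle
  duration) to cohort time series, ranked by `AIC = n ln(RSS/n) + 2k`;
* **label-retention statistics** — observed depletion rate vs the
  disposable-stem-cell expectation, return-to-quiescence and
  dormant-activation fractions with Wilson intervals, and the resting/
  dormant decomposition of the proliferating pool;
* **H2B-GFP division counting** — corrected fluorescence, neighbor-
  normalized dilution ratios with the 15%-SEM exclusion, Silverman
  critical-bandwidth multimodality testing, antimode binning into 1 / 2 /
  ≥3 divisions, and an exact contingency test between cohorts;
* **single-cell state calls** — QC gating, tdTomato recombination
  thresholds, the 0–9 G1/S index score with chemistry-dependent doubling,
  and dormant/resting/proliferating assignment;
* **synthetic cohorts** — an agent-based stochastic twin of the compartment
  model (with per-cell event histories as ground truth) plus generators for
  every input table, so the whole pipeline is testable end-to-end.

## Worked example

Simulate a noisy cross-sectional cohort under the default study conditions
(ρ = 29.2), then ask whether model selection detects that resting and
dormant cells activate at different rates:

```r
library(nscdyn)

ts <- generate_timeseries(simulation_config(seed = 1))
cfg <- fit_config(n_starts = 40, n_polish = 3, seed = 1)
f_sep <- fit_variant(ts, model_variant(), cfg)
f_sh  <- fit_variant(ts, model_variant(shared_activation = TRUE), cfg)
rank_variants(list(f_sep, f_sh))
#>                                   variant k        rss       aic delta_aic
#> 1 separate-activation+time-dep-activation 6   5.070057 -2.219873    0.0000
#> 2   shared-activation+time-dep-activation 5 164.215631 44.469723   46.6896
f_sep$params$rho
#> [1] 31.94163
```

The separate-activation model wins by ~47 AIC and recovers the generating
ratio (ρ̂ ≈ 31.9 vs 29.2): resting NSCs re-activate about thirty times
faster than dormant ones. The same cohort's tally statistics
(`return_to_quiescence_fraction()`, `resting_contribution()`) and the
division-counting pipeline (`count_divisions()`) are demonstrated in the
numbered scripts under `analysis/`, which write their tables to
`results/`; the methods vignette (`vignettes/nsc-dynamics.Rmd`) documents
the model, its assumptions and the numerical choices.

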