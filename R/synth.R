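# Synthetic cohorts: agent-based stochastic twin of the compartment model
# and generators for every input table the analyses consume.

#' Simulation configuration for synthetic cohorts
#'
#' @param params an `nsc_params` (compartment sizes are agent counts).
#' @param variant an `nsc_variant`.
#' @param protocol labeling protocol applied at observation.
#' @param n_animals mice per observation age (recycled over ages).
#' @param ages_months observation ages.
#' @param noise_cv per-mouse log-normal CV on total counts.
#' @param cells_per_mouse NSCs scored per mouse for fraction estimates.
#' @param seed mandatory integer seed.
#' @return list of class `nsc_sim_config`.
#' @export
simulation_config <- function(params = default_parameters(),
                              variant = model_variant(),
                              protocol = label_protocol(),
                              n_animals = 3,
                              ages_months = c(0.5, 1, 2, 6, 12),
                              noise_cv = 0.12, cells_per_mouse = 300,
                              seed = 0) {
  if (is.null(seed) || !is.finite(seed)) stop("a seed is mandatory")
  if (any(noise_cv < 0)) stop("noise CV must be >= 0")
  structure(list(params = params, variant = variant, protocol = protocol,
                 n_animals = n_animals, ages_months = ages_months,
                 noise_cv = noise_cv, cells_per_mouse = cells_per_mouse,
                 seed = as.integer(seed)),
            class = "nsc_sim_config")
}

# Closed-form inversion of the exponential-decay cumulative hazard:
# waiting time from t0 under hazard a * exp(-theta t). Inf = never.
activation_times <- function(t0, a, theta) {
  u <- rexp(length(t0))
  if (theta == 0) return(t0 + u / a)
  z <- exp(-theta * t0) - theta * u / a
  out <- rep(Inf, length(t0))
  pos <- is.finite(z) & z > 0
  out[pos] <- -log(z[pos]) / theta
  out
}

#' Agent-based stochastic simulation of the NSC pool
#'
#' Exact stochastic simulation of the same Markov jump process whose
#' mean-field limit is [simulate_ode()]: each agent activates from
#' dormancy/rest with the time-dependent hazard (sampled by closed-form
#' inversion), and active agents complete divisions at rate `k_div`,
#' drawing a fate (rest / stay active / deplete) at each completion.
#' Divisions are asymmetric, so the agent count never grows. Event
#' histories are recorded per agent, which makes every downstream
#' estimator auditable against ground truth.
#'
#' @param params an `nsc_params`; `d0, r0, a0` are rounded to agent counts.
#' @param variant an `nsc_variant` (time-dependent cycle duration is not
#'   supported by the agent engine).
#' @param t_max simulation horizon in days.
#' @param seed integer seed; the run is a pure function of
#'   `(params, variant, t_max, seed)`.
#' @return object of class `nsc_agents`: `events` data frame
#'   (`id, time, type` with types `activate_d, activate_r, div_rest,
#'   div_active, div_deplete`), initial states `state0`, and metadata.
#' @export
simulate_agents <- function(params = default_parameters(),
                            variant = model_variant(), t_max = 540, seed = 0) {
  stopifnot(inherits(params, "nsc_params"))
  p <- effective_params(params, variant)
  if (p$slope_cycle != 0)
    stop("agent engine supports constant cycle duration only")
  n_d <- round(p$d0); n_r <- round(p$r0); n_a <- round(p$a0)
  n <- n_d + n_r + n_a
  if (n > 1e5) stop("agent populations above 1e5 are not supported at desk scale")
  if (n == 0) stop("empty population")
  set.seed(seed)
  state0 <- rep(c("D", "R", "A"), c(n_d, n_r, n_a))
  ids <- seq_len(n)

  ev_id <- list(); ev_t <- list(); ev_ty <- list(); chunk <- 0L
  push <- function(id, t, ty) {
    chunk <<- chunk + 1L
    ev_id[[chunk]] <<- id; ev_t[[chunk]] <<- t; ev_ty[[chunk]] <<- ty
  }

  # quiescent queue
  q_id <- ids[state0 != "A"]
  q_pool <- state0[state0 != "A"]
  q_t <- rep(0, length(q_id))
  # active set
  a_id <- ids[state0 == "A"]; a_t <- rep(0, n_a)
  total_events <- 0L

  repeat {
    if (length(q_id)) {
      base <- p$alpha_d0 * ifelse(q_pool == "R", p$rho, 1)
      t_act <- if (p$alpha_d0 > 0) activation_times(q_t, base, p$theta)
               else rep(Inf, length(q_id))
      go <- is.finite(t_act) & t_act <= t_max
      if (any(go)) {
        push(q_id[go], t_act[go], ifelse(q_pool[go] == "R", 2L, 1L))
        a_id <- c(a_id, q_id[go]); a_t <- c(a_t, t_act[go])
      }
      q_id <- integer(0); q_pool <- character(0); q_t <- numeric(0)
    }
    if (!length(a_id)) break
    # run the active set to exhaustion; collect returns to rest
    r_id <- integer(0); r_t <- numeric(0)
    while (length(a_id)) {
      t_new <- a_t + rexp(length(a_id)) / p$k_div
      keep <- t_new <= t_max
      a_id <- a_id[keep]; t_new <- t_new[keep]
      if (!length(a_id)) { a_t <- numeric(0); break }
      fp <- fate_probs(p, t_new)
      u <- runif(length(a_id))
      fate <- 1L + (u > fp[, "rest"]) + (u > fp[, "rest"] + fp[, "active"])
      push(a_id, t_new, c(3L, 4L, 5L)[fate])
      total_events <- total_events + length(a_id)
      if (total_events > 100L * n)
        stop("runaway event count; check rates (k_div, fate probabilities)")
      r_id <- c(r_id, a_id[fate == 1L]); r_t <- c(r_t, t_new[fate == 1L])
      a_id <- a_id[fate == 2L]; a_t <- t_new[fate == 2L]
    }
    if (!length(r_id)) break
    q_id <- r_id; q_pool <- rep("R", length(r_id)); q_t <- r_t
  }

  types <- c("activate_d", "activate_r", "div_rest", "div_active", "div_deplete")
  events <- data.frame(id = unlist(ev_id, use.names = FALSE),
                       time = unlist(ev_t, use.names = FALSE),
                       type = unlist(ev_ty, use.names = FALSE))
  if (!nrow(events)) events <- data.frame(id = integer(0), time = numeric(0),
                                          type = integer(0))
  events$type <- factor(types[events$type], levels = types)
  structure(list(events = events, state0 = state0, n_agents = n,
                 params = p, variant = variant, t_max = t_max, seed = seed),
            class = "nsc_agents")
}

#' Observe an agent simulation at one time point
#'
#' Reconstructs every agent's state, division count, EdU label and
#' marker detectability at `t_obs` from the event history. A cell is
#' EdU+ if a division completed while its S-phase overlapped the
#' exposure window; Ki67+ (MCM2+) if active or having returned to rest
#' within the respective perdurance window. Agents that depleted are
#' dropped (they are no longer NSCs).
#'
#' @param sim an `nsc_agents` object.
#' @param t_obs observation time in days.
#' @param protocol an `nsc_protocol` (or `NULL` for no labeling).
#' @return data frame: `id, state, divisions, edu, ki67, mcm2, origin,
#'   activated_dormant_in_chase, gfp_level`.
#' @export
observe_agents <- function(sim, t_obs, protocol = label_protocol()) {
  stopifnot(inherits(sim, "nsc_agents"))
  if (t_obs < 0 || t_obs > sim$t_max) stop("t_obs outside simulated horizon")
  ev <- sim$events[sim$events$time <= t_obs, ]
  ord <- order(ev$id, ev$time)
  ev <- ev[ord, ]
  n <- sim$n_agents
  last_idx <- which(!duplicated(ev$id, fromLast = TRUE))
  last_type <- rep(NA_character_, n)
  last_type[ev$id[last_idx]] <- as.character(ev$type[last_idx])

  state <- ifelse(is.na(last_type),
                  c(D = "dormant", R = "resting", A = "active")[sim$state0],
                  ifelse(last_type == "div_rest", "resting",
                  ifelse(last_type == "div_deplete", "depleted", "active")))

  is_div <- ev$type %in% c("div_rest", "div_active", "div_deplete")
  divisions <- tabulate(ev$id[is_div], nbins = n)

  # time of last return to rest, for marker perdurance
  rest_ev <- ev[ev$type == "div_rest", ]
  t_rest <- rep(-Inf, n)
  if (nrow(rest_ev)) {
    li <- which(!duplicated(rest_ev$id, fromLast = TRUE))
    t_rest[rest_ev$id[li]] <- rest_ev$time[li]
  }
  w_ki <- protocol$ki67_perdurance_hours / 24
  w_mcm <- protocol$mcm2_perdurance_hours / 24
  ki67 <- state == "active" | (state == "resting" & (t_obs - t_rest) <= w_ki)
  mcm2 <- state == "active" | (state == "resting" & (t_obs - t_rest) <= w_mcm)

  edu <- rep(FALSE, n)
  act_chase <- rep(FALSE, n)
  if (!is.null(protocol) && protocol$exposure_days > 0) {
    wn <- label_window(protocol, t_obs, sim$params$k_div)
    if (is.finite(wn[1])) {
      lab_ev <- ev[is_div & ev$time >= wn[1] & ev$time <= wn[2], ]
      edu[unique(lab_ev$id)] <- TRUE
      ad <- ev[ev$type == "activate_d" & ev$time > wn[3], ]
      act_chase[unique(ad$id)] <- TRUE
    }
  }

  # origin of the most recent activation (initial actives count as
  # dormant-derived)
  act_ev <- ev[ev$type %in% c("activate_d", "activate_r"), ]
  origin <- ifelse(sim$state0 == "A", "dormant", NA_character_)
  if (nrow(act_ev)) {
    li <- which(!duplicated(act_ev$id, fromLast = TRUE))
    origin[act_ev$id[li]] <- ifelse(act_ev$type[li] == "activate_r",
                                    "resting", "dormant")
  }

  out <- data.frame(id = seq_len(n), state = state, divisions = divisions,
                    edu = edu, ki67 = ki67, mcm2 = mcm2, origin = origin,
                    activated_dormant_in_chase = act_chase,
                    gfp_level = 2^(-divisions))
  out[out$state != "depleted", ]
}

#' Observable summaries of an agent run at several ages
#'
#' Emits the same streams as [predict_observables()] plus ground-truth
#' summaries used to audit the label-retention estimators.
#'
#' @param sim an `nsc_agents`.
#' @param ages_days observation times.
#' @param protocol labeling protocol anchored to each age.
#' @return data frame with observables and truth columns
#'   (`truth_rtq`: labeled cells genuinely quiescent; `truth_resting_origin`:
#'   Ki67+ cells whose last activation came from rest;
#'   `truth_dormant_act`: alive cells whose dormant activation fell in
#'   the chase window).
#' @export
summarize_observables <- function(sim, ages_days, protocol = label_protocol()) {
  rows <- lapply(ages_days, function(t) {
    o <- observe_agents(sim, t, protocol)
    n <- nrow(o)
    n_edu <- sum(o$edu)
    data.frame(
      age_days = t, n_total = n,
      frac_active = mean(o$ki67),
      frac_resting_labeled = mean(o$edu & !o$ki67),
      frac_labeled = mean(o$edu),
      truth_rtq = if (n_edu) sum(o$edu & o$state == "resting") / n_edu else NA_real_,
      truth_resting_origin = if (any(o$ki67))
        mean(o$origin[o$ki67] == "resting", na.rm = TRUE) else NA_real_,
      truth_dormant_act = mean(o$activated_dormant_in_chase))
  })
  do.call(rbind, rows)
}

#' Generate a noisy cohort time series
#'
#' Cross-sectional cohort table in the `ObservedSeries` schema: the
#' deterministic observable predictions at each age plus per-mouse
#' measurement noise (log-normal, mean-preserving, on the total count;
#' binomial sampling of `cells_per_mouse` scored cells for fractions).
#'
#' @param config an `nsc_sim_config`.
#' @return an `nsc_series` data frame; the noise-free predictions are
#'   attached as `attr(, "truth")`.
#' @export
generate_timeseries <- function(config) {
  stopifnot(inherits(config, "nsc_sim_config"))
  set.seed(config$seed)
  t_days <- age_to_model_time(config$ages_months)
  pred <- predict_observables(config$params, config$variant, config$protocol,
                              t_days)
  n_mice <- rep_len(config$n_animals, length(t_days))
  m <- config$cells_per_mouse
  sigma <- sqrt(log(1 + config$noise_cv^2))
  # SEM columns carry the exact sampling-model dispersion (not the 3-mouse
  # empirical SD): with so few animals per age, empirical variances have 2
  # degrees of freedom and make inverse-variance weights heavy-tailed.
  rows <- lapply(seq_along(t_days), function(i) {
    nm <- n_mice[i]
    ntot <- pred$n_total[i] * rlnorm(nm, -sigma^2 / 2, sigma)
    fa <- rbinom(nm, m, pred$frac_active[i]) / m
    fr <- if (is.na(pred$frac_resting_labeled[i])) rep(NA_real_, nm)
          else rbinom(nm, m, pred$frac_resting_labeled[i]) / m
    mn <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    bin_sem <- function(p) sqrt(pmax(p * (1 - p), 1e-8) / m) / sqrt(nm)
    data.frame(age_months = config$ages_months[i],
               n_total_mean = mn(ntot),
               n_total_sem = pred$n_total[i] * config$noise_cv / sqrt(nm),
               frac_active_mean = mn(fa),
               frac_active_sem = bin_sem(pred$frac_active[i]),
               frac_resting_mean = mn(fr),
               frac_resting_sem = if (all(is.na(fr))) NA_real_
                                  else bin_sem(pred$frac_resting_labeled[i]),
               n_mice = nm)
  })
  out <- observed_series(do.call(rbind, rows))
  attr(out, "truth") <- pred
  out
}

#' Generate pulse-chase tallies from an agent cohort
#'
#' Runs one agent simulation and, at each age, scores
#' `cells_per_mouse` randomly sampled NSCs per mouse into the EdU x Ki67
#' cross-table. Ground-truth summaries from the same agents are attached
#' as `attr(, "truth")`.
#'
#' @param config an `nsc_sim_config`.
#' @return an `nsc_tally` data frame (one row per mouse and age).
#' @export
generate_tallies <- function(config) {
  stopifnot(inherits(config, "nsc_sim_config"))
  t_days <- age_to_model_time(config$ages_months)
  sim <- simulate_agents(config$params, config$variant,
                         t_max = max(t_days) + 1, seed = config$seed)
  n_mice <- rep_len(config$n_animals, length(t_days))
  m <- config$cells_per_mouse
  rows <- list(); truths <- list()
  for (i in seq_along(t_days)) {
    o <- observe_agents(sim, t_days[i], config$protocol)
    probs <- c(pp = mean(o$edu & o$ki67), pn = mean(o$edu & !o$ki67),
               np = mean(!o$edu & o$ki67), nn = mean(!o$edu & !o$ki67))
    for (j in seq_len(n_mice[i])) {
      cnt <- as.integer(rmultinom(1, m, probs))
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = sprintf("age%g_m%d", config$ages_months[i], j),
        age_months = config$ages_months[i],
        chase_hours = config$protocol$chase_days * 24,
        edu_pos_ki67_pos = cnt[1], edu_pos_ki67_neg = cnt[2],
        edu_neg_ki67_pos = cnt[3], edu_neg_ki67_neg = cnt[4],
        total_nsc = m)
    }
    n_edu <- sum(o$edu)
    truths[[i]] <- data.frame(
      age_months = config$ages_months[i], n_alive = nrow(o),
      truth_rtq = if (n_edu) sum(o$edu & o$state == "resting") / n_edu else NA_real_,
      truth_resting_origin = if (any(o$ki67))
        mean(o$origin[o$ki67] == "resting", na.rm = TRUE) else NA_real_,
      truth_dormant_act = mean(o$activated_dormant_in_chase))
  }
  out <- pulse_chase_tally(do.call(rbind, rows))
  attr(out, "truth") <- do.call(rbind, truths)
  out
}

#' Generate a synthetic H2B-GFP dilution-ratio dataset
#'
#' Ratios follow the dilution physics `ratio = 2^-n` times a log-normal
#' measurement factor, where `n` is the (known) number of divisions.
#' Optionally emits neighbor CTCF triplets with a controlled SEM
#' fraction to exercise the 15% exclusion rule.
#'
#' @param division_distribution named probabilities over divisions
#'   (names "1", "2", "3", ... ; "3" stands for 3-or-more).
#' @param n_cells number of EdU+ cells (>= 50).
#' @param noise_sigma_log standard deviation of the log-normal
#'   measurement noise (natural log scale).
#' @param seed integer seed.
#' @param with_neighbors also emit per-cell neighbor triplets.
#' @param neighbor_sem_fraction target SEM/mean of the neighbor triplet.
#' @return data frame `cell_id, ratio, divisions_true` (plus neighbor
#'   columns when requested).
#' @export
generate_dilution_dataset <- function(division_distribution = c("1" = 0.64, "2" = 0.24, "3" = 0.12),
                                      n_cells = 500, noise_sigma_log = 0.08,
                                      seed = 0, with_neighbors = FALSE,
                                      neighbor_sem_fraction = 0.05) {
  if (!length(division_distribution) || abs(sum(division_distribution) - 1) > 1e-9)
    stop("division_distribution must be non-empty and sum to 1")
  if (n_cells < 50) stop("n_cells must be >= 50")
  set.seed(seed)
  nd <- as.integer(names(division_distribution))
  if (anyNA(nd) || any(nd < 1)) stop("division labels must be integers >= 1")
  divisions <- sample(nd, n_cells, replace = TRUE, prob = division_distribution)
  ratio <- 2^(-divisions) * exp(rnorm(n_cells, 0, noise_sigma_log))
  out <- data.frame(cell_id = sprintf("cell%04d", seq_len(n_cells)),
                    ratio = ratio, divisions_true = divisions)
  if (with_neighbors) {
    base <- 1000
    # three neighbor values with exact mean `base` and exact SEM fraction f:
    # (base - d, base, base + d) has sd = d, sem = d/sqrt(3)
    d <- neighbor_sem_fraction * base * sqrt(3)
    out$neighbor1 <- base - d; out$neighbor2 <- base; out$neighbor3 <- base + d
    out$cell_value <- ratio * base
  }
  out
}

#' Generate a synthetic single-cell count matrix
#'
#' Emulates the statistical structure of the classifier's input:
#' negative-binomial background genes with quiescent cells at half the
#' depth of proliferating cells, state-dependent index-gene expression
#' (near-complete dropout in G0, high per-gene detection in cycling
#' cells), reporter reads determined by recombination status, and a few
#' cells failing QC. All counts are pure functions of `(arguments, seed)`.
#'
#' @param n_dormant,n_resting,n_proliferating cells per state.
#' @param chemistry "v2" or "v3"; v3 doubles all means.
#' @param index_dropout_g0 per-gene dropout of index genes in quiescent
#'   cells (detection probability is its complement).
#' @param index_mu_g1,index_size negative-binomial law of index genes in
#'   cycling cells.
#' @param n_background,n_mito background and mitochondrial gene counts.
#' @param frac_prolif_tdtomato fraction of proliferating cells carrying
#'   the recombined reporter.
#' @param frac_g2sm fraction of proliferating cells flagged G2/S/M by
#'   upstream cycle scoring.
#' @param n_qc_low_genes,n_qc_high_mito spiked-in QC-failure cells.
#' @param seed integer seed.
#' @return list with `counts` (sparse features x cells matrix),
#'   `features`, `barcodes`, `cells` (per-cell records for
#'   [assign_state()]), and `truth`.
#' @export
generate_cell_matrix <- function(n_dormant = 150, n_resting = 60,
                                 n_proliferating = 90, chemistry = "v2",
                                 index_dropout_g0 = 0.97, index_mu_g1 = 4,
                                 index_size = 2, n_background = 1200,
                                 n_mito = 12, frac_prolif_tdtomato = 0.5,
                                 frac_g2sm = 0.4, n_qc_low_genes = 12,
                                 n_qc_high_mito = 8, seed = 0) {
  check_chemistry(chemistry)
  set.seed(seed)
  chem_mult <- if (chemistry == "v3") 2 else 1
  states <- c(rep("dormant", n_dormant), rep("resting", n_resting),
              rep("proliferating", n_proliferating),
              rep("excluded", n_qc_low_genes + n_qc_high_mito))
  n_cells <- length(states)
  qc_low <- seq_len(n_qc_low_genes) + n_dormant + n_resting + n_proliferating
  qc_mito <- seq_len(n_qc_high_mito) + max(qc_low, n_dormant + n_resting + n_proliferating)

  # depth scale: quiescent cells at half the mRNA content of cycling cells
  depth <- ifelse(states == "proliferating", 2, 1)
  depth[qc_low] <- 0.15          # too few genes detected
  depth[qc_mito] <- 1

  bg_names <- sprintf("Gene%04d", seq_len(n_background))
  mito_names <- sprintf("mt-G%02d", seq_len(n_mito))
  reporter <- c("tdTomatoLoxP", "WPRE", "bGHpolyA", "eGFP", "tdTomatoCDS")
  features <- c(bg_names, mito_names, INDEX_GENES, reporter)

  # background genes: NB(mu = depth * mult, size = 1)
  bg <- matrix(rnbinom(n_background * n_cells,
                       mu = rep(depth * chem_mult, each = n_background),
                       size = 1),
               nrow = n_background)
  mito_mu <- ifelse(seq_len(n_cells) %in% qc_mito, 60, 1.5)
  mt <- matrix(rnbinom(n_mito * n_cells,
                       mu = rep(mito_mu * depth * chem_mult, each = n_mito),
                       size = 2),
               nrow = n_mito)

  cycling <- states == "proliferating"
  det_g0 <- min((1 - index_dropout_g0) * chem_mult, 1)
  idx <- matrix(0, nrow = length(INDEX_GENES), ncol = n_cells)
  for (g in seq_along(INDEX_GENES)) {
    idx[g, cycling] <- rnbinom(sum(cycling), mu = index_mu_g1 * chem_mult,
                               size = index_size)
    nq <- sum(!cycling)
    idx[g, !cycling] <- rbinom(nq, 1, det_g0) * (1 + stats::rpois(nq, 0.3))
  }

  td_true <- states == "resting" |
    (cycling & runif(n_cells) < frac_prolif_tdtomato)
  intact_mu <- ifelse(td_true, 0.05, 3) * chem_mult
  recomb_mu <- ifelse(td_true, 5, 0.02) * chem_mult
  rep_rows <- rbind(
    tdTomatoLoxP = rnbinom(n_cells, mu = intact_mu, size = 2),
    WPRE = rnbinom(n_cells, mu = recomb_mu, size = 2),
    bGHpolyA = rnbinom(n_cells, mu = recomb_mu, size = 2),
    eGFP = rnbinom(n_cells, mu = 2 * chem_mult, size = 2),
    tdTomatoCDS = rep(0, n_cells))

  counts <- rbind(bg, mt, idx, rep_rows)
  rownames(counts) <- features
  barcodes <- sprintf("CELL%05d", seq_len(n_cells))
  colnames(counts) <- barcodes

  g2sm <- cycling & runif(n_cells) < frac_g2sm
  gene_rows <- seq_len(n_background + n_mito + length(INDEX_GENES))
  tot <- colSums(counts[gene_rows, , drop = FALSE])
  mito_tot <- colSums(counts[n_background + seq_len(n_mito), , drop = FALSE])
  cells <- data.frame(barcode = barcodes,
                      genes_detected = colSums(counts[gene_rows, , drop = FALSE] > 0),
                      mito_fraction = ifelse(tot > 0, mito_tot / tot, 0),
                      intact_reads = counts["tdTomatoLoxP", ],
                      recombined_reads = counts["WPRE", ] + counts["bGHpolyA", ],
                      chemistry = chemistry, g2sm_flag = g2sm,
                      stringsAsFactors = FALSE)
  for (g in INDEX_GENES) cells[[g]] <- counts[g, ]
  rownames(cells) <- NULL

  truth <- data.frame(barcode = barcodes, true_state = states,
                      tdtomato_true = td_true, g2sm_flag = g2sm,
                      stringsAsFactors = FALSE)
  list(counts = Matrix::Matrix(counts, sparse = TRUE), features = features,
       barcodes = barcodes, cells = cells, truth = truth)
}

#' Write a synthetic cell matrix as an MTX triplet
#'
#' @param mat result of [generate_cell_matrix()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cell_matrix <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                            "truth.csv"))
  Matrix::writeMM(mat$counts, paths[1])
  writeLines(mat$features, paths[2])
  writeLines(mat$barcodes, paths[3])
  write.csv(mat$truth, paths[4], row.names = FALSE)
  invisible(paths)
}
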