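# H2B-GFP label-dilution division counting.

#' Corrected total cellular fluorescence
#'
#' `CTCF = integrated density - area * mean background fluorescence`.
#' Negative results are returned, flagged via the `"negative"` attribute.
#'
#' @param integrated_density integrated density of the nucleus (a.u., >= 0).
#' @param area region-of-interest area (> 0).
#' @param background_mean mean background fluorescence per unit area.
#' @return numeric vector of corrected fluorescence values with a
#'   logical `"negative"` attribute.
#' @export
ctcf <- function(integrated_density, area, background_mean) {
  if (any(area <= 0)) stop("area must be > 0")
  if (any(integrated_density < 0)) stop("integrated_density must be >= 0")
  v <- integrated_density - area * background_mean
  attr(v, "negative") <- v < 0
  v
}

#' Neighbor-normalized dilution ratio
#'
#' The GFP fluorescence of an EdU+ NSC relative to the mean of 2-3
#' neighboring undivided (EdU-) NSCs. Measurements whose neighbor SEM
#' exceeds 15% of the neighbor mean are excluded (normalization deemed
#' unreliable). The SEM uses the sample standard deviation (n-1).
#'
#' @param cell_value CTCF of the EdU+ cell (> 0).
#' @param neighbor_values CTCF of 2-3 EdU- neighbors (> 0).
#' @param sem_threshold exclusion threshold on SEM/mean.
#' @return list of class `ratio_measurement`: `ratio`,
#'   `neighbor_sem_fraction`, `excluded`, and the inputs.
#' @export
dilution_ratio <- function(cell_value, neighbor_values, sem_threshold = 0.15) {
  nn <- length(neighbor_values)
  if (nn < 2 || nn > 3) stop("2-3 neighbor values are required")
  if (cell_value <= 0 || any(neighbor_values <= 0))
    stop("all fluorescence values must be > 0")
  m <- mean(neighbor_values)
  sem_frac <- sd(neighbor_values) / sqrt(nn) / m
  structure(list(ratio = cell_value / m, neighbor_sem_fraction = sem_frac,
                 excluded = sem_frac > sem_threshold,
                 cell_value = cell_value, neighbor_values = neighbor_values),
            class = "ratio_measurement")
}

# Number of modes of a Gaussian KDE at bandwidth h.
kde_n_modes <- function(x, h, n_grid = 512) {
  d <- density(x, bw = h, kernel = "gaussian", n = n_grid,
               from = min(x) - 3 * h, to = max(x) + 3 * h)
  s <- sign(diff(d$y))
  s <- s[s != 0]
  if (!length(s)) return(1L)
  r <- rle(s)$values
  # grid spans min(x)-3h .. max(x)+3h, so the density decays at both edges
  # and every mode is a +1 -> -1 transition
  max(sum(r[-length(r)] > 0 & r[-1] < 0), 1L)
}

# Smallest bandwidth at which the Gaussian KDE has at most k modes
# (mode count is non-increasing in h for the Gaussian kernel).
critical_bandwidth <- function(x, k, tol = 1e-4, n_grid = 512) {
  hi <- max(x) - min(x)
  if (hi <= 0) stop("degenerate (constant) data")
  lo <- hi / 1000
  while (kde_n_modes(x, lo, n_grid) <= k) {
    lo <- lo / 10
    if (lo < hi * 1e-9) return(lo)  # data cannot show more than k modes
  }
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    if (kde_n_modes(x, mid, n_grid) <= k) hi <- mid else lo <- mid
    if (hi / lo < 1 + tol) break
  }
  hi
}

# Silverman critical-bandwidth bootstrap p-value for H0: at most k modes.
silverman_p <- function(x, k, n_boot = 500) {
  n <- length(x)
  h <- critical_bandwidth(x, k)
  xbar <- mean(x)
  scale <- 1 / sqrt(1 + h^2 / var(x))
  exceed <- 0L
  for (b in seq_len(n_boot)) {
    y <- xbar + (x[sample.int(n, n, replace = TRUE)] - xbar + h * rnorm(n)) * scale
    if (kde_n_modes(y, h) > k) exceed <- exceed + 1L
  }
  exceed / n_boot
}

#' Estimate the number of modes of a dilution-ratio distribution
#'
#' Sequential Silverman critical-bandwidth bootstrap tests: the returned
#' `k` is the smallest number of modes for which the null hypothesis "at
#' most k modes" is not rejected at `alpha`. Ratios are analyzed on the
#' log2 scale, where each division shifts the distribution by one unit.
#'
#' @param ratios included dilution ratios (>= 50 values).
#' @param alpha test level for each sequential test.
#' @param n_boot bootstrap replicates per test.
#' @param seed integer seed (the procedure is seeded and reproducible).
#' @param k_max largest k tested.
#' @return integer mode count with attribute `"p_values"`.
#' @export
estimate_mode_count <- function(ratios, alpha = 0.05, n_boot = 500, seed = 0,
                                k_max = 5) {
  if (length(ratios) < 50) stop("need at least 50 included ratios")
  if (any(ratios <= 0)) stop("ratios must be > 0")
  x <- log2(ratios)
  if (sd(x) == 0 || max(x) == min(x)) stop("degenerate (constant) ratio data")
  set.seed(seed)
  pv <- numeric(0)
  for (k in seq_len(k_max)) {
    p <- silverman_p(x, k, n_boot)
    pv[k] <- p
    if (p >= alpha) return(structure(k, p_values = pv))
  }
  warning("no k <= ", k_max, " accepted; returning k_max")
  structure(k_max, p_values = pv)
}

#' Locate modes and antimodes and build division bins
#'
#' Evaluates the kernel density at the critical bandwidth for `k` modes;
#' modes are its local maxima and antimodes the local minima between
#' them. The k-1 antimodes become bin boundaries mapping ratios to
#' division counts: the highest-ratio bin is 1 division (every EdU+ cell
#' divided at least once; there is no 0-division bin), the next 2, and
#' the lowest ">=3" (3 and more divisions are not distinguishable).
#'
#' @param ratios included dilution ratios.
#' @param k mode count, typically from [estimate_mode_count()].
#' @return object of class `division_binning`: `k`, `modes` and
#'   `boundaries` on the natural ratio scale (descending), and bin
#'   `labels`.
#' @export
locate_modes_antimodes <- function(ratios, k) {
  if (any(ratios <= 0)) stop("ratios must be > 0")
  x <- log2(ratios)
  h <- critical_bandwidth(x, k, n_grid = 2048)
  # nudge the bandwidth up if the finite grid still resolves a spurious
  # extra ripple at the critical value
  for (i in 1:10) {
    if (kde_n_modes(x, h, n_grid = 2048) <= k) break
    h <- h * 1.02
  }
  d <- density(x, bw = h, kernel = "gaussian", n = 2048,
               from = min(x) - 3 * h, to = max(x) + 3 * h)
  y <- d$y
  imax <- which(diff(sign(diff(y))) == -2) + 1
  if (length(imax) != k)
    stop("k = ", k, " is inconsistent with the density shape (found ",
         length(imax), " modes)")
  anti <- integer(0)
  if (k > 1) {
    anti <- vapply(seq_len(k - 1), function(j) {
      seg <- imax[j]:imax[j + 1]
      seg[which.min(y[seg])]
    }, integer(1))
  }
  modes <- sort(2^d$x[imax], decreasing = TRUE)
  boundaries <- sort(2^d$x[anti], decreasing = TRUE)
  n_bins <- min(k, 3)
  labels <- c("1", "2", ">=3")[seq_len(n_bins)]
  if (k >= 3) labels[3] <- ">=3"
  structure(list(k = k, modes = modes, boundaries = boundaries,
                 labels = labels, bandwidth = h),
            class = "division_binning")
}

#' Assign a division count to a dilution ratio
#'
#' Deterministic lookup against the bin boundaries: ratios above the
#' first antimode are "1" division, then "2", then ">=3". A ratio lying
#' exactly on a boundary goes to the higher-division bin.
#'
#' @param binning a `division_binning`.
#' @param ratio numeric vector of included ratios.
#' @return character vector of bin labels.
#' @export
assign_divisions <- function(binning, ratio) {
  stopifnot(inherits(binning, "division_binning"))
  if (any(!is.finite(ratio))) stop("excluded or non-finite measurements cannot be assigned")
  b <- binning$boundaries
  if (length(b) > 2) b <- b[1:2]  # 3+ divisions are one bin
  vapply(ratio, function(r) {
    bin <- 1L + sum(r <= b)
    binning$labels[min(bin, length(binning$labels))]
  }, character(1))
}

#' Dilution-ratio pipeline: mode estimation, binning, per-cell assignment
#'
#' @param ratios included dilution ratios.
#' @param cohort optional cohort labels (same length), producing a
#'   cohort-by-bin contingency table.
#' @param alpha,n_boot,seed passed to [estimate_mode_count()].
#' @return list with `k`, `binning`, `assignments`, and (with cohorts)
#'   `table`.
#' @export
count_divisions <- function(ratios, cohort = NULL, alpha = 0.05, n_boot = 500,
                            seed = 0) {
  k <- estimate_mode_count(ratios, alpha = alpha, n_boot = n_boot, seed = seed)
  binning <- locate_modes_antimodes(ratios, as.integer(k))
  bins <- assign_divisions(binning, ratios)
  out <- list(k = as.integer(k), binning = binning,
              assignments = factor(bins, levels = binning$labels))
  if (!is.null(cohort)) out$table <- table(cohort = cohort, bin = out$assignments)
  out
}

# Upper bound on the number of tables sharing the margins.
count_tables_bound <- function(rs, cs) {
  prod(choose(rs[-length(rs)] + length(cs) - 1, length(cs) - 1))
}

#' Exact contingency test for an r x c table
#'
#' Conditional-on-margins exact test: the p-value is the total
#' probability, under the multivariate hypergeometric null, of all
#' tables with the observed margins whose probability does not exceed
#' the observed table's. Tables are enumerated exhaustively, so margins
#' must be small.
#'
#' @param tab matrix of non-negative integer counts (rows = cohorts,
#'   columns = division bins).
#' @param max_tables guard on the enumeration size.
#' @return two-sided p-value.
#' @export
exact_contingency_test <- function(tab, max_tables = 1e7) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (count_tables_bound(rs, cs) > max_tables)
    stop("margins too large for exhaustive enumeration; use a Monte Carlo test")
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  logp_obs <- log_const - sum(lgamma(tab + 1))

  r <- length(rs); cc <- length(cs)
  total <- 0
  # enumerate rows 1..r-1; the last row is determined by the margins
  recurse <- function(row, col_left, lg_acc) {
    if (row == r) {
      if (any(col_left < 0)) return()
      lp <- log_const - lg_acc - sum(lgamma(col_left + 1))
      if (lp <= logp_obs + 1e-8) total <<- total + exp(lp)
      return()
    }
    s <- rs[row]
    fill <- function(j, left, avail, lg_row) {
      if (j == cc) {
        if (left > avail[cc]) return()
        recurse(row + 1, {a <- avail; a[cc] <- a[cc] - left; a},
                lg_acc + lg_row + lgamma(left + 1))
        return()
      }
      for (v in 0:min(left, avail[j])) {
        a <- avail; a[j] <- a[j] - v
        fill(j + 1, left - v, a, lg_row + lgamma(v + 1))
      }
    }
    fill(1, s, col_left, 0)
    NULL
  }
  recurse(1, cs, 0)
  min(total, 1)
}
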