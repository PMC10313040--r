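# Auto-similarity function (ASF): the two-sample Kuiper statistic applied
# to the same evolving variable at two timepoints,
#
#   Sigma(t_i, t_j) = sup_v [F_i(v) - F_j(v)]_+ + sup_v [F_j(v) - F_i(v)]_+
#
# where F_t is the empirical CDF of the DNA-content sample at time t.
# Sigma is 0 for indistinguishable distributions (full asynchrony) and 1
# for fully separated ones (full synchrony). Being rank-based it is
# invariant under monotone transformations, which suits cyclic DNA-content
# data whose "starting point" is arbitrary.

#' Empirical cumulative distribution function of a measurement sample
#'
#' Builds a right-continuous step CDF: `support` holds the sorted distinct
#' values and `cum_frac` the cumulative fraction of observations at or
#' below each. Ties accumulate mass at a single support point.
#'
#' @param sample Non-empty numeric vector of finite measurements.
#' @return An object of class `empirical_cdf` with fields `support`,
#'   `cum_frac`, `n`, and usable as a function via [eval_cdf()].
#' @examples
#' F <- empirical_cdf(c(1, 2, 2, 4))
#' eval_cdf(F, 2)  # 0.75
#' @export
empirical_cdf <- function(sample) {
  if (length(sample) == 0L) stop_invalid("`sample` must be non-empty")
  if (!is.numeric(sample) || any(!is.finite(sample))) {
    stop_invalid("`sample` must be finite numeric")
  }
  tab <- sort(unique(sample))
  counts <- tabulate(match(sample, tab), nbins = length(tab))
  structure(
    list(support = tab, cum_frac = cumsum(counts) / length(sample),
         n = length(sample)),
    class = "empirical_cdf"
  )
}

#' Evaluate an empirical CDF
#'
#' @param cdf An [empirical_cdf()] object.
#' @param v Numeric evaluation points.
#' @return `F(v)` = fraction of the sample at or below each `v`.
#' @export
eval_cdf <- function(cdf, v) {
  if (!inherits(cdf, "empirical_cdf")) {
    stop_invalid("`cdf` must be an empirical_cdf object")
  }
  idx <- findInterval(v, cdf$support)
  out <- numeric(length(v))
  out[idx > 0] <- cdf$cum_frac[idx[idx > 0]]
  out
}

#' @export
print.empirical_cdf <- function(x, ...) {
  cat(sprintf("<empirical_cdf> n = %d, %d distinct values in [%g, %g]\n",
              x$n, length(x$support), min(x$support), max(x$support)))
  invisible(x)
}

#' Two-sample Kuiper statistic (auto-similarity function)
#'
#' Computes `Sigma = max(0, sup(F1 - F2)) + max(0, sup(F2 - F1))` between
#' the empirical CDFs of two samples. For step CDFs it suffices to evaluate
#' both differences at every pooled data point (just below the pooled
#' minimum both CDFs are 0). Each supremum is floored at zero, so
#' `Sigma(x, x) = 0` exactly and `Sigma` lies in `[0, 1]` always.
#'
#' @param x1,x2 Non-empty numeric samples.
#' @return The statistic, a number in `[0, 1]`.
#' @examples
#' kuiper_statistic(1:3, 1:3)        # 0: identical distributions
#' kuiper_statistic(1:3, 10:12)      # 1: fully separated
#' kuiper_statistic(c(1, 2, 3), c(2, 3, 4))  # 1/3
#' @export
kuiper_statistic <- function(x1, x2) {
  if (length(x1) == 0L || length(x2) == 0L) {
    stop_invalid("both samples must be non-empty")
  }
  if (!is.numeric(x1) || !is.numeric(x2) ||
      any(!is.finite(x1)) || any(!is.finite(x2))) {
    stop_invalid("samples must be finite numeric")
  }
  pooled <- sort(unique(c(x1, x2)))
  s1 <- sort(x1)
  s2 <- sort(x2)
  f1 <- findInterval(pooled, s1) / length(s1)
  f2 <- findInterval(pooled, s2) / length(s2)
  max(0, max(f1 - f2)) + max(0, max(f2 - f1))
}

#' Auto-similarity series over successive timepoint pairs
#'
#' Applies [kuiper_statistic()] to each consecutive pair of timepoint
#' columns of a population timecourse. A synchronized population starts
#' near 1 and decays toward the asynchronous finite-sample floor as cells
#' drift apart in cycle position.
#'
#' @param timecourse A `population_timecourse` (from [simulate_population()]
#'   or [read_events_table()]).
#' @return An object of class `asf_series`: data frame columns `t_start`,
#'   `t_end`, `value`, plus attribute `normalized = FALSE`.
#' @export
asf_successive <- function(timecourse) {
  m <- timecourse_matrix(timecourse)
  t_grid <- timecourse_times(timecourse)
  if (ncol(m) < 2L) stop_invalid("need at least 2 timepoints")
  k <- ncol(m) - 1L
  vals <- vapply(seq_len(k), function(j) {
    kuiper_statistic(m[, j], m[, j + 1L])
  }, numeric(1))
  new_asf_series(t_grid[seq_len(k)], t_grid[seq_len(k) + 1L], vals,
                 normalized = FALSE)
}

#' Construct an ASF series from explicit values
#'
#' Mainly useful for importing externally computed auto-similarity values
#' (e.g. from another instrument pipeline) or for averaging replicate
#' series before fitting.
#'
#' @param t_start,t_end Start and end times (h) of each successive pair.
#' @param value ASF value per pair; must lie in `[0, 1]` unless
#'   `normalized = TRUE`.
#' @param normalized Whether the values are already normalized to the
#'   initial pair.
#' @return An `asf_series`.
#' @export
asf_series <- function(t_start, t_end, value, normalized = FALSE) {
  if (length(t_start) != length(t_end) || length(t_end) != length(value)) {
    stop_invalid("`t_start`, `t_end`, `value` must have equal length")
  }
  if (any(!is.finite(value)) || (!normalized && any(value < 0 | value > 1))) {
    stop_invalid("unnormalized ASF values must lie in [0, 1]")
  }
  if (any(t_end <= t_start)) stop_invalid("each pair needs t_end > t_start")
  new_asf_series(t_start, t_end, value, normalized = normalized)
}

new_asf_series <- function(t_start, t_end, value, normalized) {
  structure(
    data.frame(t_start = t_start, t_end = t_end, value = value),
    normalized = normalized,
    class = c("asf_series", "data.frame")
  )
}

#' @export
print.asf_series <- function(x, ...) {
  cat(sprintf("<asf_series> %d successive pairs%s\n", nrow(x),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Pairwise auto-similarity matrix
#'
#' [kuiper_statistic()] for every unordered pair of timepoints; symmetric
#' with an exactly-zero diagonal. The band next to the diagonal equals the
#' successive-pair series.
#'
#' @inheritParams asf_successive
#' @return A symmetric numeric matrix with timepoint labels.
#' @export
asf_matrix <- function(timecourse) {
  m <- timecourse_matrix(timecourse)
  t_grid <- timecourse_times(timecourse)
  if (ncol(m) < 2L) stop_invalid("need at least 2 timepoints")
  k <- ncol(m)
  out <- matrix(0, k, k, dimnames = list(t_grid, t_grid))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      out[i, j] <- out[j, i] <- kuiper_statistic(m[, i], m[, j])
    }
  }
  out
}

#' Normalize an ASF series to its initial value
#'
#' Divides every value by the first (the earliest post-release pair), so
#' replicate experiments with different absolute initial ASF become
#' comparable. Asynchronous control series should not be normalized: their
#' raw flat trend is the point of the control.
#'
#' @param series An `asf_series`.
#' @return The normalized `asf_series` (first value exactly 1).
#' @export
normalize_series <- function(series) {
  if (!inherits(series, "asf_series")) {
    stop_invalid("`series` must be an asf_series")
  }
  if (series$value[1] == 0) {
    abort_cycleASF("cannot normalize: first ASF value is 0",
                   "degenerate_normalization")
  }
  new_asf_series(series$t_start, series$t_end,
                 series$value / series$value[1], normalized = TRUE)
}

#' Fit a logistic decay to a desynchronization curve
#'
#' Least-squares fit of
#' `Sigma(t) = lower + (upper - lower) / (1 + exp(rate * (t - t_half)))`
#' to an ASF series. Each successive pair `(t_i, t_{i+1})` is assigned the
#' time `t_{i+1}`, the moment the comparison becomes available. The fitted
#' `rate` (1/h) is the package's desynchronization-rate summary; `t_half`
#' is reported alongside.
#'
#' Fitting is multi-start Nelder-Mead/BFGS over data-driven
#' initializations (`upper` = first value, `lower` = last value, `t_half`
#' = mid-range crossing, `rate` in {0.05, 0.15, 0.5}), with constraints
#' keeping `lower >= 0` and, for unnormalized series, `upper <= 1`. A mild
#' ridge penalty on the rate (`rate_penalty * rate^2`, default 0.1)
#' regularizes the fit: on a coarse sampling grid an unconstrained
#' logistic can chase single-interval steps with arbitrarily large rates
#' when the decay is weak, and the penalty — negligible at physically
#' plausible rates below ~0.3/h, dominant above ~0.5/h — keeps the rate
#' an identifiable summary of the decay envelope. The reported `rss`
#' excludes the penalty.
#'
#' @param series An `asf_series` with at least 4 pairs.
#' @param rate_penalty Ridge coefficient on the squared rate (default 0.1;
#'   0 disables regularization).
#' @return An object of class `logistic_fit`: list with `upper`, `lower`,
#'   `rate`, `t_half`, `rss`, `fitted`, `times`.
#' @export
fit_logistic_decay <- function(series, rate_penalty = 0.1) {
  if (!inherits(series, "asf_series")) {
    stop_invalid("`series` must be an asf_series")
  }
  if (nrow(series) < 4L) {
    stop_invalid("need at least 4 pairs to fit 4 parameters")
  }
  check_scalar_number(rate_penalty, "rate_penalty", nonneg = TRUE)
  tt <- series$t_end
  yy <- series$value
  upper_cap <- if (isTRUE(attr(series, "normalized"))) 1.1 * max(yy) else 1

  model <- function(p, t) p[2] + (p[1] - p[2]) / (1 + exp(p[3] * (t - p[4])))
  objective <- function(p) {
    if (p[2] < 0 || p[1] < p[2] || p[3] < 0 || p[1] > upper_cap) return(1e6)
    sum((yy - model(p, tt))^2) + rate_penalty * p[3]^2
  }

  y_first <- yy[1]
  y_last <- yy[length(yy)]
  mid <- (max(yy) + min(yy)) / 2
  t_half0 <- tt[which.min(abs(yy - mid))]
  starts <- list()
  for (r in c(0.05, 0.15, 0.5)) {
    starts[[length(starts) + 1L]] <-
      c(max(y_first, y_last), min(y_first, y_last), r, t_half0)
    starts[[length(starts) + 1L]] <-
      c(max(yy), min(yy), r, mean(range(tt)))
  }
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, objective, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      # polish with BFGS from the simplex optimum
      fit2 <- tryCatch(
        stats::optim(fit$par, objective, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) fit
      )
      if (fit2$value <= fit$value) fit <- fit2
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (is.null(best)) {
    abort_cycleASF("logistic fit failed to converge from any start",
                   "fit_failure")
  }
  p <- best$par
  structure(
    list(upper = p[1], lower = p[2], rate = p[3], t_half = p[4],
         rss = sum((yy - model(p, tt))^2), fitted = model(p, tt), times = tt),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> upper %.4g, lower %.4g, rate %.4g 1/h, t_half %.4g h (rss %.3g)\n",
    x$upper, x$lower, x$rate, x$t_half, x$rss
  ))
  invisible(x)
}

#' Estimate cell-cycle period variability from a desynchronization curve
#'
#' Simulation-based inverse inference: for each candidate period SD on
#' `grid`, run `reps` synchronized-release simulations, average their
#' normalized successive-pair ASF series, and score the sum of squared
#' differences to the (normalized) observed series. The arg-min candidate
#' is the estimate; the full discrepancy profile is returned so the user
#' can judge identifiability. Normalizing both sides makes the estimator
#' insensitive to the absolute initial ASF.
#'
#' @param observed An `asf_series` measured on the same time grid as the
#'   simulations (normalized automatically if it is not already).
#' @param grid Non-empty numeric vector of candidate `sigma_tau` values, h.
#' @param reps Simulations averaged per candidate (default 5).
#' @param base A [simulation_config()] giving everything but `sigma_tau`
#'   (cells, grid, mean period, seed). The default starts simulated cells
#'   at the G1/S boundary, matching
#'   [emulate_synchronized_experiment()]; the estimator's simulations
#'   should mirror the design of the observed experiment.
#' @return List with `estimate` (h), `profile` (data frame `sigma_tau`,
#'   `discrepancy`), and `reps`.
#' @export
estimate_sigma_tau <- function(observed, grid, reps = 5,
                               base = simulation_config(init_age_fraction = 0.5)) {
  if (!inherits(observed, "asf_series")) {
    stop_invalid("`observed` must be an asf_series")
  }
  if (length(grid) == 0L || !is.numeric(grid)) {
    stop_invalid("`grid` must be a non-empty numeric vector")
  }
  if (!inherits(base, "simulation_config")) {
    stop_invalid("`base` must be a simulation_config")
  }
  expected_ends <- base$t_grid[-1]
  if (nrow(observed) != length(expected_ends) ||
      any(abs(observed$t_end - expected_ends) > 1e-8)) {
    stop_invalid("`observed` and `base$t_grid` must share the same time grid")
  }
  obs <- if (isTRUE(attr(observed, "normalized"))) observed else normalize_series(observed)

  disc <- vapply(seq_along(grid), function(gi) {
    sims <- vapply(seq_len(reps), function(r) {
      cfg <- simulation_config(
        n_cells = base$n_cells, t_grid = base$t_grid,
        noise = noise_spec(
          mean_tau = base$noise$mean_tau, sigma_tau = grid[gi],
          sigma_dna0 = base$noise$sigma_dna0,
          family_tau = base$noise$family_tau,
          family_dna = base$noise$family_dna,
          tau_min = base$noise$tau_min
        ),
        init_mode = "synchronized", base_dna0 = base$base_dna0,
        fluorescence_scale = base$fluorescence_scale,
        init_age_fraction = base$init_age_fraction,
        seed = derive_seed(base$seed, gi * 1000L + r)
      )
      normalize_series(asf_successive(simulate_population(cfg)))$value
    }, numeric(nrow(obs)))
    avg <- rowMeans(sims)
    sum((avg - obs$value)^2)
  }, numeric(1))

  list(
    estimate = grid[which.min(disc)],
    profile = data.frame(sigma_tau = grid, discrepancy = disc),
    reps = reps
  )
}
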