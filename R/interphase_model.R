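# Single-cell interphase DNA-content model.
#
# A cell's DNA content over one interphase (0 <= t <= tau) follows a
# logistic (sigmoidal) synthesis curve rising from dna0 in G1 toward
# dna_max = 2 * dna0 in G2:
#
#   dna(t) = dna0 * (1 + 1 / (1 + exp(-beta * (t - s))))
#
# With beta and s tied to the period tau (beta = 24 / (3 tau) = 8 / tau,
# s = 2 tau / 3) the S-phase window occupies the middle third of the cycle
# centred on s, so a 24 h cycle has an 8 h S phase. Population variability
# enters as error-in-variables noise on tau and dna0 (see noise_spec()).

#' Cell-cycle realization parameters
#'
#' Construct the parameter set for one realized cell cycle: initial DNA
#' content, post-synthesis maximum (always exactly twice the initial
#' content, since synthesis duplicates the genome), logistic synthesis
#' steepness `beta`, synthesis midpoint time `s`, and cycle period `tau`.
#'
#' Most users will not call this directly; [derive_cycle_params()] fills in
#' `beta`, `s` and `dna_max` from `tau` and `dna0`.
#'
#' @param dna0 Initial DNA content (arbitrary units, > 0).
#' @param dna_max Post-synthesis DNA content; must equal `2 * dna0`.
#' @param beta Synthesis steepness (1/h, > 0).
#' @param s Synthesis midpoint time (h, strictly inside `(0, tau)`).
#' @param tau Cycle period (h, > 0).
#' @return An object of class `cycle_params`.
#' @seealso [derive_cycle_params()], [dna_deterministic()]
#' @export
cycle_params <- function(dna0, dna_max, beta, s, tau) {
  check_scalar_number(dna0, "dna0", positive = TRUE)
  check_scalar_number(dna_max, "dna_max", positive = TRUE)
  check_scalar_number(beta, "beta", positive = TRUE)
  check_scalar_number(s, "s")
  check_scalar_number(tau, "tau", positive = TRUE)
  if (abs(dna_max - 2 * dna0) > 1e-9 * dna0) {
    stop_invalid("`dna_max` must equal 2 * dna0 (faithful genome duplication)")
  }
  if (s <= 0 || s >= tau) {
    stop_invalid("`s` must satisfy 0 < s < tau")
  }
  structure(
    list(dna0 = dna0, dna_max = dna_max, beta = beta, s = s, tau = tau),
    class = "cycle_params"
  )
}

#' @export
print.cycle_params <- function(x, ...) {
  cat(sprintf(
    "<cycle_params> tau = %.3g h, dna0 = %.3g a.u., beta = %.3g 1/h, s = %.3g h\n",
    x$tau, x$dna0, x$beta, x$s
  ))
  invisible(x)
}

#' Derive full cycle parameters from period and initial DNA content
#'
#' Reduces the interphase model to two free parameters by expressing the
#' synthesis steepness and midpoint as functions of the period:
#' `beta = 24 / (3 * tau)` (equivalently `8 / tau`) and `s = 2 * tau / 3`,
#' with `dna_max = 2 * dna0`. At the reference period of 24 h this places
#' the synthesis midpoint at 16 h and gives an S phase spanning the middle
#' third of the cycle (8 h), matching commonly reported phase durations.
#'
#' @param tau Cycle period in hours (> 0).
#' @param dna0 Initial DNA content in arbitrary units (> 0).
#' @return A [cycle_params()] object.
#' @examples
#' p <- derive_cycle_params(24, 1)
#' p$beta  # 1/3
#' p$s     # 16
#' @export
derive_cycle_params <- function(tau, dna0) {
  check_scalar_number(tau, "tau", positive = TRUE)
  check_scalar_number(dna0, "dna0", positive = TRUE)
  cycle_params(
    dna0 = dna0,
    dna_max = 2 * dna0,
    beta = 24 / (3 * tau),
    s = 2 * tau / 3,
    tau = tau
  )
}

#' Deterministic single-cell DNA content during interphase
#'
#' Evaluates the logistic synthesis model
#' `dna(t) = dna0 * (1 + 1 / (1 + exp(-beta * (t - s))))` at time `t`
#' within one cycle. The curve is non-decreasing, equals `1.5 * dna0`
#' exactly at `t = s`, and approaches (without reaching) `2 * dna0` as the
#' sigmoid saturates. Times outside `[0, tau]` are an error: wrapping a
#' cell across divisions is the population simulator's job.
#'
#' @param t Time within the cycle, hours; vectorized.
#' @param params A [cycle_params()] object.
#' @return DNA content in the same arbitrary units as `params$dna0`.
#' @export
dna_deterministic <- function(t, params) {
  if (!inherits(params, "cycle_params")) {
    stop_invalid("`params` must be a cycle_params object")
  }
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop_invalid("`t` must be finite numeric")
  }
  if (any(t < 0 | t > params$tau)) {
    abort_cycleASF(
      sprintf("`t` must lie in [0, tau = %g]; cycle wrapping is handled by the population simulator", params$tau),
      "out_of_domain"
    )
  }
  params$dna0 * (1 + stats::plogis(params$beta * (t - params$s)))
}

#' Population noise model for cycle period and initial DNA content
#'
#' Describes the error-in-variables noise applied per cell per cycle: the
#' effective period is `mean_tau` plus a zero-mean error drawn from
#' `family_tau`, and the effective initial DNA content is a base value
#' plus an error drawn from `family_dna`. Normal draws are
#' rejection-resampled until the period is at least `tau_min` and the DNA
#' content is positive, so no non-physical cycles are produced.
#'
#' The Poisson families are a comparison mode: period draws are
#' `tau' ~ Poisson(mean_tau)` (integer hours, variance equal to the mean),
#' and DNA draws are `dna0' = base * P / lambda` with `P ~ Poisson(lambda)`
#' (`lambda = 100`), a mean-preserving relative-noise construction.
#'
#' @param mean_tau Population mean cycle period, hours (> 0).
#' @param sigma_tau Period standard deviation, hours (>= 0; used by the
#'   normal family, ignored by the Poisson family whose variance is
#'   `mean_tau` by construction).
#' @param sigma_dna0 Initial-DNA standard deviation, arbitrary units (>= 0).
#' @param family_tau `"normal"` or `"poisson"`.
#' @param family_dna `"normal"` or `"poisson"`.
#' @param tau_min Minimum admissible period, hours (default 4; must satisfy
#'   `0 < tau_min < mean_tau`).
#' @param poisson_lambda Rate of the auxiliary Poisson draw used by the
#'   Poisson DNA family (default 100).
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec(mean_tau = 24, sigma_tau = 3, sigma_dna0 = 0.05)
#' @export
noise_spec <- function(mean_tau, sigma_tau, sigma_dna0,
                       family_tau = c("normal", "poisson"),
                       family_dna = c("normal", "poisson"),
                       tau_min = 4, poisson_lambda = 100) {
  family_tau <- match.arg(family_tau)
  family_dna <- match.arg(family_dna)
  check_scalar_number(mean_tau, "mean_tau", positive = TRUE)
  check_scalar_number(sigma_tau, "sigma_tau", nonneg = TRUE)
  check_scalar_number(sigma_dna0, "sigma_dna0", nonneg = TRUE)
  check_scalar_number(tau_min, "tau_min", positive = TRUE)
  check_scalar_number(poisson_lambda, "poisson_lambda", positive = TRUE)
  if (tau_min >= mean_tau) {
    stop_invalid("`tau_min` must satisfy 0 < tau_min < mean_tau")
  }
  structure(
    list(
      mean_tau = mean_tau, sigma_tau = sigma_tau, sigma_dna0 = sigma_dna0,
      family_tau = family_tau, family_dna = family_dna,
      tau_min = tau_min, poisson_lambda = poisson_lambda
    ),
    class = "noise_spec"
  )
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf(
    "<noise_spec> tau ~ %s(mean %.3g h, sd %.3g h), dna0 noise ~ %s(sd %.3g a.u.), tau_min %.3g h\n",
    x$family_tau, x$mean_tau, x$sigma_tau, x$family_dna, x$sigma_dna0, x$tau_min
  ))
  invisible(x)
}

# Vectorized rejection sampler: n effective periods under `noise`.
# Cap of 1000 resampling rounds guards against degenerate specs.
sample_periods <- function(n, noise) {
  draw <- function(m) {
    if (noise$family_tau == "normal") {
      noise$mean_tau + stats::rnorm(m, 0, noise$sigma_tau)
    } else {
      stats::rpois(m, noise$mean_tau)
    }
  }
  out <- draw(n)
  bad <- which(out < noise$tau_min)
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > 1000L) {
      abort_cycleASF(
        "resampling cap (1000) exceeded while drawing admissible periods",
        "resampling_cap"
      )
    }
    out[bad] <- draw(length(bad))
    bad <- bad[out[bad] < noise$tau_min]
  }
  out
}

# Vectorized rejection sampler: n effective initial DNA contents.
sample_dna0 <- function(n, noise, base_dna0) {
  draw <- function(m) {
    if (noise$family_dna == "normal") {
      base_dna0 + stats::rnorm(m, 0, noise$sigma_dna0)
    } else {
      base_dna0 * stats::rpois(m, noise$poisson_lambda) / noise$poisson_lambda
    }
  }
  out <- draw(n)
  bad <- which(out <= 0)
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > 1000L) {
      abort_cycleASF(
        "resampling cap (1000) exceeded while drawing positive DNA content",
        "resampling_cap"
      )
    }
    out[bad] <- draw(length(bad))
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Draw one noisy cell-cycle realization
#'
#' Samples an effective period `tau' = mean_tau + eps_tau` and effective
#' initial DNA content `dna0' = base_dna0 + eps_dna0` from the families
#' configured in `noise` (rejection-resampled until `tau' >= tau_min` and
#' `dna0' > 0`), then derives the full parameter set via
#' [derive_cycle_params()]. With both standard deviations zero the draw is
#' deterministic.
#'
#' @param noise A [noise_spec()] object.
#' @param base_dna0 Baseline initial DNA content, arbitrary units.
#' @param seed Optional integer seed for a self-contained draw; `NULL`
#'   (default) uses the ambient RNG stream.
#' @return A [cycle_params()] object.
#' @export
sample_cycle <- function(noise, base_dna0 = 1, seed = NULL) {
  if (!inherits(noise, "noise_spec")) {
    stop_invalid("`noise` must be a noise_spec object")
  }
  check_scalar_number(base_dna0, "base_dna0", positive = TRUE)
  with_seed(seed, {
    tau <- sample_periods(1L, noise)
    dna0 <- sample_dna0(1L, noise, base_dna0)
    derive_cycle_params(tau, dna0)
  })
}

#' Cell-cycle phase at a time within one cycle
#'
#' Assigns G1, S or G2 under the convention that S is the length-`tau/3`
#' interval centred on the synthesis midpoint `s = 2 tau / 3`: G1 on
#' `[0, tau/2)`, S on `[tau/2, 5 tau/6)`, G2 on `[5 tau/6, tau)`. Intervals
#' are half-open so every admissible time has exactly one label and the
#' phase durations are exactly `tau/2`, `tau/3` and `tau/6`.
#'
#' @param t Time within the cycle, hours; vectorized.
#' @param tau Cycle period, hours.
#' @return Character vector of `"G1"`, `"S"`, `"G2"`.
#' @examples
#' phase_at(c(6, 16, 22), tau = 24)
#' @export
phase_at <- function(t, tau) {
  check_scalar_number(tau, "tau", positive = TRUE)
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop_invalid("`t` must be finite numeric")
  }
  if (any(t < 0 | t >= tau)) {
    abort_cycleASF(
      sprintf("`t` must lie in [0, tau = %g)", tau),
      "out_of_domain"
    )
  }
  out <- character(length(t))
  out[t < tau / 2] <- "G1"
  out[t >= tau / 2 & t < 5 * tau / 6] <- "S"
  out[t >= 5 * tau / 6] <- "G2"
  out
}
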