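test_that("empirical_cdf follows step-function semantics with ties", {
  F <- empirical_cdf(c(1, 2, 2, 4))
  expect_equal(eval_cdf(F, 2), 0.75)
  expect_equal(eval_cdf(F, 4), 1)
  expect_equal(eval_cdf(F, 0.999), 0)
  expect_equal(eval_cdf(F, 2.5), 0.75)  # right-continuous plateau
  expect_equal(F$cum_frac[length(F$cum_frac)], 1)
  expect_true(all(diff(F$cum_frac) >= 0))

  single <- empirical_cdf(5)
  expect_equal(eval_cdf(single, c(4.9, 5, 5.1)), c(0, 1, 1))

  expect_error(empirical_cdf(numeric(0)), class = "cycleASF_invalid_input")
})

test_that("kuiper_statistic reproduces analytic cases", {
  expect_identical(kuiper_statistic(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5)), 0)
  expect_identical(kuiper_statistic(1:3, 10:12), 1)
  expect_equal(kuiper_statistic(c(1, 2, 3), c(2, 3, 4)), 1 / 3)
  expect_error(kuiper_statistic(numeric(0), 1:3), class = "cycleASF_invalid_input")
})

test_that("kuiper_statistic matches the brute-force oracle on random pairs", {
  withr::with_seed(2024, {
    for (i in 1:200) {
      n1 <- sample(1:30, 1)
      n2 <- sample(1:30, 1)
      # mix of continuous and heavily tied integer samples
      if (i %% 2 == 0) {
        x1 <- rnorm(n1)
        x2 <- rnorm(n2, mean = runif(1, -1, 1))
      } else {
        x1 <- sample(0:5, n1, replace = TRUE)
        x2 <- sample(0:5, n2, replace = TRUE)
      }
      expect_equal(kuiper_statistic(x1, x2), kuiper_bruteforce(x1, x2),
                   tolerance = 1e-12)
    }
  })
})

test_that("kuiper_statistic is symmetric, bounded and rank-invariant", {
  withr::with_seed(99, {
    for (i in 1:50) {
      x1 <- rnorm(sample(2:40, 1))
      x2 <- rnorm(sample(2:40, 1), mean = runif(1, -2, 2))
      s <- kuiper_statistic(x1, x2)
      expect_gte(s, 0)
      expect_lte(s, 1)
      expect_identical(s, kuiper_statistic(x2, x1))
      # strictly increasing transforms leave the statistic unchanged
      expect_equal(kuiper_statistic(exp(x1), exp(x2)), s, tolerance = 1e-12)
      expect_equal(kuiper_statistic(atan(x1) * 3 + 7, atan(x2) * 3 + 7), s,
                   tolerance = 1e-12)
    }
  })
})

test_that("asf_successive applies the statistic to consecutive columns", {
  tc <- quick_sync(seed = 55)
  series <- asf_successive(tc)
  expect_s3_class(series, "asf_series")
  expect_equal(nrow(series), 11)
  expect_equal(series$t_end, seq(8, 88, by = 8))
  expect_equal(series$value[3],
               kuiper_statistic(tc$measurements[, 3], tc$measurements[, 4]))

  # zero noise: distinct point masses per timepoint, every pair separated
  tc0 <- emulate_synchronized_experiment(noise_spec(24, 0, 0), 50, seed = 1)
  expect_true(all(asf_successive(tc0)$value == 1))

  # identical columns give identically zero
  flat <- tc
  for (j in 2:12) flat$measurements[, j] <- flat$measurements[, 1]
  expect_true(all(asf_successive(flat)$value == 0))
})

test_that("asf_matrix is symmetric, zero-diagonal and consistent", {
  tc <- quick_sync(n_cells = 150, seed = 77)
  M <- asf_matrix(tc)
  expect_equal(dim(M), c(12, 12))
  expect_identical(M, t(M))
  expect_true(all(diag(M) == 0))
  series <- asf_successive(tc)
  expect_equal(M[cbind(1:11, 2:12)], series$value)
})

test_that("normalize_series rescales to the initial pair", {
  s <- asf_series(seq(0, 32, 8), seq(8, 40, 8), c(0.8, 0.6, 0.4, 0.3, 0.2))
  n1 <- normalize_series(s)
  expect_equal(n1$value, c(1, 0.75, 0.5, 0.375, 0.25))
  expect_true(attr(n1, "normalized"))
  # idempotence
  expect_equal(normalize_series(n1)$value, n1$value)

  s0 <- asf_series(c(0, 8), c(8, 16), c(0, 0.5))
  expect_error(normalize_series(s0),
               class = "cycleASF_degenerate_normalization")
})

test_that("fit_logistic_decay recovers noise-free generating parameters", {
  tt <- seq(8, 88, by = 8)
  truth <- c(upper = 0.869, lower = 0.127, rate = 0.15, t_half = 40)
  y <- truth["lower"] + (truth["upper"] - truth["lower"]) /
    (1 + exp(truth["rate"] * (tt - truth["t_half"])))
  s <- asf_series(tt - 8, tt, as.numeric(y))
  fit <- fit_logistic_decay(s, rate_penalty = 0)
  expect_lt(fit$rss, 1e-8)
  expect_equal(fit$upper, 0.869, tolerance = 1e-3)
  expect_equal(fit$lower, 0.127, tolerance = 1e-3)
  expect_equal(fit$rate, 0.15, tolerance = 1e-2)
  expect_equal(fit$t_half, 40, tolerance = 1e-2)
})

test_that("fit_logistic_decay handles a constant series as a plateau", {
  s <- asf_series(seq(0, 72, 8), seq(8, 80, 8), rep(0.4, 10))
  fit <- fit_logistic_decay(s)
  expect_lt(fit$rss, 1e-6)
  # any parameterization is acceptable as long as the curve is flat:
  expect_lt(max(abs(fit$fitted - 0.4)), 1e-3)
})

test_that("simulated synchronized experiments yield a positive decay rate", {
  tc <- emulate_synchronized_experiment(default_noise(), 1000, seed = 404)
  series <- asf_successive(tc)
  fit <- fit_logistic_decay(series)
  expect_gt(fit$rate, 0)
  expect_gt(fit$upper, fit$lower)
  # convergence: the tail of the series sits below the head
  expect_lt(mean(series$value[9:11]), mean(series$value[1:3]))
})

test_that("estimate_sigma_tau returns the only candidate on a 1-point grid", {
  tc <- quick_sync(n_cells = 200, seed = 3)
  obs <- asf_successive(tc)
  base <- simulation_config(n_cells = 100, init_age_fraction = 0.5, seed = 50)
  est <- estimate_sigma_tau(obs, grid = 2.5, reps = 2, base = base)
  expect_equal(est$estimate, 2.5)
  expect_equal(nrow(est$profile), 1)

  bad <- asf_series(seq(0, 16, 8), seq(8, 24, 8), c(0.9, 0.5, 0.3))
  expect_error(estimate_sigma_tau(bad, grid = 1:3, base = base),
               class = "cycleASF_invalid_input")
})
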