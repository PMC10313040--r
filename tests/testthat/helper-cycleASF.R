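# Shared fixtures: everything is generated in code at test time.

default_noise <- function(sigma_tau = 3, sigma_dna0 = 0.05, mean_tau = 24, ...) {
  noise_spec(mean_tau = mean_tau, sigma_tau = sigma_tau,
             sigma_dna0 = sigma_dna0, ...)
}

# Independent brute-force Kuiper oracle: evaluate both empirical CDFs at
# every pooled data point with <= semantics, take the two floored suprema.
# Deliberately naive (double loop over pooled points) and kept free of any
# package internals.
kuiper_bruteforce <- function(x1, x2) {
  pts <- sort(unique(c(x1, x2)))
  d_plus <- 0
  d_minus <- 0
  for (v in pts) {
    f1 <- sum(x1 <= v) / length(x1)
    f2 <- sum(x2 <= v) / length(x2)
    d_plus <- max(d_plus, f1 - f2)
    d_minus <- max(d_minus, f2 - f1)
  }
  max(0, d_plus) + max(0, d_minus)
}

# Small synchronized / asynchronous simulations reused across tests.
quick_sync <- function(sigma_tau = 3, n_cells = 400, seed = 101, ...) {
  emulate_synchronized_experiment(default_noise(sigma_tau), n_cells = n_cells,
                                  seed = seed, ...)
}

# Synthetic three-population DNA mixture with DJF-style structure:
# G1 Gaussian, G2 Gaussian at double position, broadened uniform S bridge.
djf_mixture_sample <- function(n, frac_g1 = 0.6, frac_s = 0.25, frac_g2 = 0.15,
                               mu1 = 50, sd1 = 2.5, sd2 = 5, seed = 5) {
  stopifnot(abs(frac_g1 + frac_s + frac_g2 - 1) < 1e-9)
  set.seed(seed)
  comp <- sample(c("g1", "s", "g2"), n, replace = TRUE,
                 prob = c(frac_g1, frac_s, frac_g2))
  x <- numeric(n)
  x[comp == "g1"] <- stats::rnorm(sum(comp == "g1"), mu1, sd1)
  x[comp == "g2"] <- stats::rnorm(sum(comp == "g2"), 2 * mu1, sd2)
  ns <- sum(comp == "s")
  u <- stats::runif(ns, mu1, 2 * mu1)
  x[comp == "s"] <- u + stats::rnorm(ns, 0, sd1 + (u - mu1) / mu1 * (sd2 - sd1))
  x
}
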