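# Naive, loop-based transcriptions of the scoring formulas, kept deliberately
# independent of the vectorized implementations they cross-check.

oracle_shtc <- function(deltas) {
  m <- 0
  for (d in deltas) if (abs(d) > m) m <- abs(d)
  out <- numeric(length(deltas))
  for (i in seq_along(deltas)) out[i] <- abs(deltas[i]) * 100 / m
  out
}

oracle_thermal_accuracy <- function(shtc, perceived) {
  total <- 0
  for (i in seq_along(shtc)) total <- total + (100 - abs(shtc[i] - perceived[i]))
  total / length(shtc)
}

oracle_awareness <- function(confidence, accuracy) {
  100 - abs(confidence - accuracy)
}

oracle_cardiac_accuracy <- function(recorded, perceived) {
  total <- 0
  for (i in seq_along(recorded)) {
    total <- total + 100 * (1 - abs(recorded[i] - perceived[i]) / recorded[i])
  }
  total / length(recorded)
}

# Independent fine-grid quadrature oracle for the correlation Bayes factor:
# Gauss hypergeometric via its Euler integral (stats::integrate), marginal
# likelihood via Simpson's rule on a fixed rho grid.
oracle_jzs_bf <- function(r, n, kappa = 1, n_grid = 8001) {
  h2f1_euler <- function(z) {
    f <- function(t) t^(-0.5) * (1 - t)^(n - 2) * (1 - z * t)^(-0.5)
    exp(lgamma(n - 0.5) - lgamma(0.5) - lgamma(n - 1)) *
      stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
  }
  lik <- function(rho) {
    (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^(1.5 - n) *
      h2f1_euler((1 + rho * r) / 2)
  }
  eps <- 1e-10
  rho <- seq(-1 + eps, 1 - eps, length.out = n_grid)
  g <- vapply(rho, function(p) {
    lik(p) * stats::dbeta((p + 1) / 2, 1 / kappa, 1 / kappa) / 2
  }, numeric(1))
  h <- rho[2] - rho[1]
  w <- rep(c(4, 2), length.out = n_grid - 2)
  num <- h / 3 * (g[1] + sum(w * g[2:(n_grid - 1)]) + g[n_grid])
  num / lik(0)
}

# small default study for tests that just need plausible data
tiny_sim <- function(n = 6, seed = 1, ...) {
  simulate_study(sim_config(n_participants = n, seed = seed, ...),
                 include_series = FALSE)
}

perfect_config <- function(n = 5, ...) {
  sim_config(
    n_participants = n,
    vas_gain_mean = 1, vas_gain_sd = 0,
    vas_bias_mean = 0, vas_bias_sd = 0,
    vas_noise_sd = 0,
    confidence_bias = 0, confidence_noise_sd = 0,
    hct_attenuation_mean = 1, hct_attenuation_sd = 0,
    hct_count_noise_sd = 0,
    ...
  )
}
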