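test_that("the correlation Bayes factor matches an independent quadrature oracle", {
  cases <- expand.grid(r = c(0, 0.08, 0.3, -0.25, 0.6, -0.8),
                       n = c(10, 31, 80))
  for (i in seq_len(nrow(cases))) {
    got <- jzs_correlation_bf(cases$r[i], cases$n[i])
    want <- oracle_jzs_bf(cases$r[i], cases$n[i])
    expect_equal(got, want, tolerance = 1e-6)
  }
  # two-sided default is symmetric in the sign of r
  expect_equal(jzs_correlation_bf(0.4, 25), jzs_correlation_bf(-0.4, 25))
  # at r = 0 the evidence for the null grows with n
  bfs <- jzs_correlation_bf(rep(0, 4), c(5, 15, 50, 150))
  expect_true(all(diff(bfs) < 0))
  # wider priors penalize the alternative more at small r
  expect_lt(jzs_correlation_bf(0.1, 31, kappa = 2),
            jzs_correlation_bf(0.1, 31, kappa = 1))

  expect_error(jzs_correlation_bf(1, 31), class = "thermo_input_error")
  expect_error(jzs_correlation_bf(0.5, 2), class = "thermo_input_error")
})

test_that("paired t tests follow the closed form and sign convention", {
  got <- paired_ttest(c(2, 4, 6), c(1, 2, 3))  # differences 1, 2, 3
  expect_equal(got$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$estimate, 2)

  flipped <- paired_ttest(c(1, 2, 3), c(2, 4, 6))
  expect_equal(flipped$t, -got$t)
  expect_equal(flipped$p, got$p)

  expect_error(paired_ttest(1:5, 1:5), class = "thermo_degenerate_error")
  expect_error(paired_ttest(1:2, 3:4), class = "thermo_input_error")
})

test_that("correlation tables carry the family-wise Bonferroni cutoff and BFs", {
  set.seed(2)
  d <- tibble::tibble(a = rnorm(31), c = rnorm(31), e = rnorm(31))
  d$b <- d$a  # identical vectors
  d$d <- 2 + 3 * d$a  # positive affine image
  got <- pearson_with_bonferroni(d, list(c("a", "b"), c("a", "d"),
                                         c("a", "c"), c("a", "e")))
  expect_equal(unique(got$cutoff), 0.05 / 4)  # printed as 0.012 in use
  expect_equal(got$r[1], 1)
  expect_equal(got$r[2], 1, tolerance = 1e-12)
  expect_true(all(got$bf10 > 0))
  expect_equal(got$n, rep(31L, 4))

  const <- tibble::tibble(x = rnorm(10), y = rep(1, 10))
  expect_error(pearson_with_bonferroni(const, list(c("x", "y"))),
               class = "thermo_degenerate_error")
})

test_that("Cronbach's alpha matches its closed forms", {
  # duplicated columns are perfectly consistent
  x <- rnorm(40)
  expect_equal(cronbach_alpha(cbind(x, x, x))$alpha, 1)

  # k = 2 with equal sample variances: alpha = 2 rho / (1 + rho)
  x1 <- c(1, 2, 3, 4, 5, 7)
  x2 <- c(2, 1, 4, 3, 7, 5)  # permutation: identical sample variance
  rho <- cor(x1, x2)
  expect_equal(cronbach_alpha(cbind(x1, x2))$alpha, 2 * rho / (1 + rho),
               tolerance = 1e-12)

  # independent columns: alpha near 0
  set.seed(3)
  m <- matrix(rnorm(4e4), ncol = 4)
  expect_lt(abs(cronbach_alpha(m)$alpha), 0.05)

  expect_error(cronbach_alpha(matrix(1, 5, 3)),
               class = "thermo_degenerate_error")
  expect_error(cronbach_alpha(matrix(rnorm(10), ncol = 1)),
               class = "thermo_input_error")
})

test_that("the Fisher-z sample size helper reproduces the design calculation", {
  expect_equal(required_n_correlation(0.49, power = 0.8, alpha = 0.05), 31L)
  # monotone in power, floor of 4 as r -> 1
  expect_gte(required_n_correlation(0.49, power = 0.9),
             required_n_correlation(0.49, power = 0.8))
  expect_equal(required_n_correlation(0.99999), 4L)
  expect_error(required_n_correlation(0), class = "thermo_input_error")
  expect_error(required_n_correlation(0.5, power = 1),
               class = "thermo_input_error")
})

test_that("the intensity mixed model reports Wald tests and Bonferroni contrasts", {
  sim <- tiny_sim(n = 10, seed = 21)
  scored <- standardize_changes(sim$thermal_trials)
  fit <- fit_intensity_model(scored, "real_delta")
  expect_s3_class(fit, "thermo_intensity_fit")
  expect_equal(nrow(fit$contrasts), choose(5, 2))
  expect_true(all(fit$contrasts$p_adjusted >= 0 &
                    fit$contrasts$p_adjusted <= 1))
  # contrasts are lower - higher: increasing warming gives negative estimates
  expect_lt(fit$contrasts$estimate[fit$contrasts$contrast ==
                                     "intensity0 - intensity100"], 0)
  g <- glance(fit)
  expect_gt(g$chisq, 0)
  expect_equal(g$df, 4)
  expect_equal(g$n_obs, 150)
  # emmeans per level recover the per-level means of a balanced design
  per_level <- dplyr::summarise(
    dplyr::group_by(scored, intensity), m = mean(real_delta))
  expect_equal(fit$emmeans$emmean, per_level$m, tolerance = 1e-6)

  expect_error(
    fit_intensity_model(scored[scored$participant_id == "p01", ],
                        "real_delta"),
    class = "thermo_input_error")
})

test_that("a constant outcome yields zero contrast estimates", {
  sim <- tiny_sim(n = 5, seed = 22)
  d <- sim$thermal_trials
  d$flat <- 7
  fit <- suppressWarnings(fit_intensity_model(d, "flat"))
  expect_equal(fit$contrasts$estimate, rep(0, 10), tolerance = 1e-10)
})

test_that("the mixed model tolerates missing trials", {
  sim <- tiny_sim(n = 8, seed = 23)
  d <- sim$thermal_trials
  d$real_delta[sample.int(nrow(d), 12)] <- NA
  fit <- fit_intensity_model(d, "real_delta")
  expect_equal(fit$n_obs, nrow(d) - 12)
  expect_true(is.finite(glance(fit)$chisq))
})

test_that("regressions recover exact coefficients and flag collinearity", {
  set.seed(30)
  d <- tibble::tibble(x = rnorm(20), z = rnorm(20))
  d$y <- 2 * d$x  # noise-free
  fit <- suppressWarnings(fit_regressions(d, model = "custom", dv = "y",
                                          predictors = c("x", "z")))
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "x"], 2,
               tolerance = 1e-10)
  expect_equal(nrow(fit$coefficients), 3)  # intercept + 2 predictors
  expect_true(all(fit$wald$term %in% c("(Intercept)", "x", "z")))

  d$x2 <- d$x
  expect_error(
    fit_regressions(d, model = "custom", dv = "y",
                    predictors = c("x", "x2")),
    class = "thermo_collinear_error")
  expect_error(
    fit_regressions(d[1:3, ], model = "custom", dv = "y",
                    predictors = c("x", "z")),
    class = "thermo_input_error")
})

test_that("permuting the outcome keeps the family-wise error near nominal", {
  set.seed(31)
  sim <- tiny_sim(n = 31, seed = 32)
  items <- sim$questionnaire_items
  wide <- subscales_wide(score_subscales(items))
  acc <- score_participants(sim)$thermal_iacc
  hits <- vapply(1:150, function(i) {
    wide$thermal_iacc <- sample(acc)
    fit <- fit_regressions(wide, "sensibility")
    any(fit$coefficients$p_bonferroni < 0.05, na.rm = TRUE)
  }, logical(1))
  # Bonferroni keeps the family-wise rate at or below ~5%
  expect_lte(mean(hits), 0.10)
})

test_that("all reported p values are probabilities and adjustments only increase them", {
  sim <- tiny_sim(n = 8, seed = 33)
  scored <- standardize_changes(sim$thermal_trials)
  fit <- fit_intensity_model(scored, "perceived_vas")
  raw <- 2 * pnorm(-abs(fit$contrasts$statistic))
  expect_true(all(fit$contrasts$p_adjusted >= raw - 1e-12))
  expect_true(all(fit$wald$p >= 0 & fit$wald$p <= 1))
  expect_equal(pmin(1, raw * nrow(fit$contrasts)), fit$contrasts$p_adjusted,
               tolerance = 1e-10)
})
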