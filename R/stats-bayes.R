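# Gauss hypergeometric 2F1(a, b; c; z) by power series, valid for |z| < 1.
# Converges quickly for the arguments used here (a = b = 1/2, c = n - 1/2,
# z = (1 + rho * r) / 2 < 1).
hyp2f1_series <- function(a, b, c, z, tol = 1e-15, max_terms = 100000L) {
  term <- 1
  total <- 1
  for (k in seq_len(max_terms)) {
    term <- term * (a + k - 1) * (b + k - 1) / ((c + k - 1) * k) * z
    total <- total + term
    if (abs(term) < tol * abs(total)) return(total)
  }
  warn("2F1 series did not fully converge; result may be inaccurate.")
  total
}

# rho-dependent part of the exact sampling density of a Pearson r given the
# population correlation rho (constant factors cancel in the Bayes factor)
correlation_reduced_likelihood <- function(rho, r, n) {
  vapply(rho, function(p) {
    exp(((n - 1) / 2) * log1p(-p^2) + (1.5 - n) * log1p(-p * r)) *
      hyp2f1_series(0.5, 0.5, n - 0.5, (1 + p * r) / 2)
  }, numeric(1))
}

#' Default Bayes factor for a Pearson correlation (JZS / stretched beta)
#'
#' Computes the two-sided default Bayes factor BF10 for the hypothesis that a
#' population correlation rho is nonzero, from the observed Pearson `r` and
#' sample size `n` alone. The prior on rho is the "stretched beta":
#' `(rho + 1) / 2 ~ Beta(1/kappa, 1/kappa)`, uniform on \[-1, 1\] at the
#' default width `kappa = 1` (the JASP default). The marginal likelihood is
#' obtained by numerical integration of the exact reduced likelihood of `r`
#' over rho; BF10 is its ratio to the likelihood at rho = 0.
#'
#' @param r Observed Pearson correlation(s), strictly inside (-1, 1).
#' @param n Sample size(s), >= 3.
#' @param kappa Stretched-beta prior width (default 1).
#' @return BF10 value(s) > 0. Values below 1 favour the null.
#' @examples
#' jzs_correlation_bf(0.08, 31)
#' @export
jzs_correlation_bf <- function(r, n, kappa = 1) {
  if (length(n) == 1) n <- rep(n, length(r))
  stopifnot(length(r) == length(n))
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("`r` must lie strictly inside (-1, 1); |r| = 1 is infinite evidence.",
          class = "thermo_input_error")
  }
  if (any(n < 3)) {
    abort("`n` must be at least 3.", class = "thermo_input_error")
  }
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0) {
    abort("`kappa` must be a single positive number.",
          class = "thermo_input_error")
  }
  purrr::map2_dbl(r, n, function(ri, ni) {
    prior <- function(rho) dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa) / 2
    num <- integrate(function(rho) {
      correlation_reduced_likelihood(rho, ri, ni) * prior(rho)
    }, -1, 1, rel.tol = 1e-10, subdivisions = 500L)$value
    num / correlation_reduced_likelihood(0, ri, ni)
  })
}

#' Sample size for detecting a correlation (Fisher-z approximation)
#'
#' Closed-form power calculation for a two-sided test of a Pearson
#' correlation: `n = ((z_{1-alpha/2} + z_{power}) / atanh(r))^2 + 3`,
#' rounded up.
#'
#' @param r Expected population correlation, `0 < r < 1`.
#' @param power Target power (default 0.8).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Required sample size (integer).
#' @examples
#' required_n_correlation(0.49)
#' @export
required_n_correlation <- function(r, power = 0.8, alpha = 0.05) {
  if (!is.numeric(r) || length(r) != 1 || r <= 0 || r >= 1) {
    abort("`r` must be a single value in (0, 1).", class = "thermo_input_error")
  }
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1) {
    abort("`power` and `alpha` must lie in (0, 1).",
          class = "thermo_input_error")
  }
  as.integer(ceiling(((qnorm(1 - alpha / 2) + qnorm(power)) / atanh(r))^2 + 3))
}
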