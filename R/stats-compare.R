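#' Paired t test between two per-participant score vectors
#'
#' Classical paired t on the differences `x - y`. Used to compare the two
#' interoceptive modalities; passing the cardiac scores as `x` and the
#' thermal scores as `y` yields a negative t when thermal accuracy is higher.
#'
#' @param x,y Paired numeric vectors of equal length >= 3 (pairs with any
#'   missing value are dropped).
#' @return A one-row tibble: `estimate` (mean difference), `t`, `df`, `p`,
#'   `conf_low`, `conf_high`, `n`.
#' @examples
#' paired_ttest(c(2, 3, 4), c(1, 1, 1))
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    abort("At least 3 complete pairs are required.",
          class = "thermo_input_error")
  }
  d <- x - y
  if (sd(d) == 0) {
    abort("Differences have zero variance; the t statistic is undefined.",
          class = "thermo_degenerate_error")
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble(
    estimate = unname(tt$estimate),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    conf_low = tt$conf.int[1],
    conf_high = tt$conf.int[2],
    n = length(x)
  )
}

#' Bonferroni-corrected Pearson correlations with default Bayes factors
#'
#' Computes Pearson's r (complete cases, two-sided t-approximation p value)
#' for each requested variable pair, a family-wise Bonferroni significance
#' cutoff `alpha_family / number of pairs`, and the default JZS Bayes factor
#' [jzs_correlation_bf()] for each correlation.
#'
#' @param data A data frame holding the variables.
#' @param pairs A list of length-2 character vectors naming the variable
#'   pairs to correlate.
#' @param alpha_family Family-wise alpha divided over the pairs
#'   (default 0.05).
#' @param kappa Prior width for the Bayes factor (default 1).
#' @return A tibble with one row per pair: `var1`, `var2`, `n`, `r`, `p`,
#'   `cutoff`, `significant`, `bf10`.
#' @examples
#' d <- data.frame(a = rnorm(20), b = rnorm(20))
#' pearson_with_bonferroni(d, list(c("a", "b")))
#' @export
pearson_with_bonferroni <- function(data, pairs, alpha_family = 0.05,
                                    kappa = 1) {
  stopifnot(is.data.frame(data), is.list(pairs), length(pairs) >= 1)
  cutoff <- alpha_family / length(pairs)
  purrr::map_dfr(pairs, function(pr) {
    stopifnot(length(pr) == 2, all(pr %in% names(data)))
    x <- data[[pr[1]]]; y <- data[[pr[2]]]
    keep <- complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 4) {
      abort(sprintf("Pair %s-%s has fewer than 4 complete cases.",
                    pr[1], pr[2]), class = "thermo_input_error")
    }
    if (sd(x) == 0 || sd(y) == 0) {
      abort(sprintf("Variable with zero variance in pair %s-%s; r undefined.",
                    pr[1], pr[2]), class = "thermo_degenerate_error")
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate)
    tibble(
      var1 = pr[1], var2 = pr[2], n = length(x), r = r, p = ct$p.value,
      cutoff = cutoff, significant = ct$p.value < cutoff,
      bf10 = if (abs(r) < 1) jzs_correlation_bf(r, length(x), kappa) else Inf
    )
  })
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability over a participants-by-items score
#' matrix: `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))`,
#' with n-1 sample variances. Rows with any missing value are dropped.
#'
#' @param items A numeric matrix or data frame, one column per item (k >= 2).
#' @return A one-row tibble: `alpha`, `k_items`, `n_obs`.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(1.2, 2.1, 2.9, 4.2))
#' cronbach_alpha(m)
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  storage.mode(m) <- "double"
  m <- m[complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2) {
    abort("At least 2 items are required.", class = "thermo_input_error")
  }
  if (nrow(m) < 2) {
    abort("At least 2 complete observations are required.",
          class = "thermo_input_error")
  }
  total_var <- var(rowSums(m))
  if (total_var == 0) {
    abort("Total-score variance is zero; alpha is undefined.",
          class = "thermo_degenerate_error")
  }
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
  tibble(alpha = alpha, k_items = k, n_obs = nrow(m))
}
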