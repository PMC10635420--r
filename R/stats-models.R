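#' Mixed-model test of the stimulation-intensity effect
#'
#' Fits a random-intercept linear mixed model
#' `dv ~ intensity + (1 | participant_id)` with intensity as a categorical
#' within-subject predictor (REML by default), reports a Type III Wald
#' chi-square test for the intensity term, and computes all pairwise
#' intensity contrasts on the estimated marginal means with Bonferroni
#' adjustment over the full pair set. Contrast degrees of freedom are
#' asymptotic (normal). Missing trials are simply absent rows; the model
#' tolerates unbalanced data.
#'
#' @param trials A data frame with columns `participant_id`, `intensity`,
#'   and the outcome named by `dv`; one row per trial.
#' @param dv Name of the outcome column (e.g. `"real_delta"`,
#'   `"perceived_vas"`, `"trial_accuracy"`).
#' @param reml Fit by REML (default) or ML.
#' @param contrasts Also compute pairwise marginal-mean contrasts (default
#'   `TRUE`); disable to speed up large Monte-Carlo runs that only need the
#'   omnibus Wald test.
#' @return An object of class `thermo_intensity_fit` with elements `model`
#'   (the `lmerMod`), `wald` (term, chisq, df, p), `contrasts` (pairwise
#'   level differences: estimate, se, statistic, adjusted p), `emmeans`
#'   (per-level marginal means), `varcomp`, `dv`, `n_obs`, `n_participants`.
#'   Contrasts are `lower level - higher level`, so warming that grows with
#'   intensity yields negative estimates.
#' @examples
#' sim <- simulate_study(sim_config(n_participants = 6, seed = 3),
#'                       include_series = FALSE)
#' fit <- fit_intensity_model(sim$thermal_trials, "real_delta")
#' fit$wald
#' @export
fit_intensity_model <- function(trials, dv, reml = TRUE,
                                contrasts = TRUE) {
  stopifnot(is.data.frame(trials), is.character(dv), length(dv) == 1)
  need <- c("participant_id", "intensity", dv)
  if (!all(need %in% names(trials))) {
    abort(paste("`trials` needs columns", paste(need, collapse = ", ")),
          class = "thermo_input_error")
  }
  d <- trials %>%
    filter(!is.na(.data[[dv]]), !is.na(.data$intensity)) %>%
    mutate(
      .dv = .data[[dv]],
      intensity = factor(.data$intensity,
                         levels = sort(unique(.data$intensity)))
    )
  if (n_distinct(d$participant_id) < 2) {
    abort("At least 2 participants are required to identify the random intercept.",
          class = "thermo_input_error")
  }
  if (nlevels(d$intensity) < 2) {
    abort("At least 2 intensity levels are required.",
          class = "thermo_input_error")
  }
  m <- withCallingHandlers(
    lme4::lmer(.dv ~ intensity + (1 | participant_id), data = d, REML = reml,
               contrasts = list(intensity = "contr.sum")),
    message = function(m) invokeRestart("muffleMessage")
  )
  if (lme4::isSingular(m)) {
    warn(paste0("Singular mixed-model fit for dv `", dv,
                "`: random-intercept variance estimated at the boundary ",
                "(likely ~0 between-participant variance)."))
  }
  aov <- car::Anova(m, type = 3, test.statistic = "Chisq")
  wald <- tibble(
    term = rownames(aov),
    chisq = aov[["Chisq"]],
    df = aov[["Df"]],
    p = aov[["Pr(>Chisq)"]]
  )
  emm_tab <- contrast_tab <- NULL
  if (contrasts) {
    emm <- emmeans::emmeans(m, ~intensity, lmer.df = "asymptotic")
    ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "bonferroni"))
    stat_col <- intersect(c("t.ratio", "z.ratio"), names(ctr))[1]
    contrast_tab <- tibble(
      contrast = as.character(ctr$contrast),
      estimate = ctr$estimate,
      se = ctr$SE,
      statistic = ctr[[stat_col]],
      p_adjusted = ctr$p.value
    )
    emm_tab <- as_tibble(as.data.frame(emm))
  }
  vc <- as.data.frame(lme4::VarCorr(m))
  structure(
    list(
      model = m,
      wald = wald,
      emmeans = emm_tab,
      contrasts = contrast_tab,
      varcomp = tibble(group = vc$grp, variance = vc$vcov, sd = vc$sdcor),
      dv = dv,
      reml = reml,
      n_obs = nrow(d),
      n_participants = n_distinct(d$participant_id)
    ),
    class = "thermo_intensity_fit"
  )
}

#' @export
print.thermo_intensity_fit <- function(x, ...) {
  cat(sprintf("<intensity mixed model: %s ~ intensity + (1 | participant)>\n",
              x$dv))
  cat(sprintf("  %d observations, %d participants, %s fit\n", x$n_obs,
              x$n_participants, if (x$reml) "REML" else "ML"))
  w <- x$wald[x$wald$term == "intensity", ]
  cat(sprintf("  Type III Wald: chisq(%d) = %.2f, p = %.3g\n",
              w$df, w$chisq, w$p))
  invisible(x)
}

#' @method tidy thermo_intensity_fit
#' @export
tidy.thermo_intensity_fit <- function(x, effects = c("contrasts", "fixed"),
                                      ...) {
  effects <- match.arg(effects)
  if (effects == "contrasts") return(x$contrasts)
  fe <- summary(x$model)$coefficients
  tibble(term = rownames(fe), estimate = fe[, "Estimate"],
         std_error = fe[, "Std. Error"], statistic = fe[, "t value"])
}

#' @method glance thermo_intensity_fit
#' @export
glance.thermo_intensity_fit <- function(x, ...) {
  w <- x$wald[x$wald$term == "intensity", ]
  tibble(
    chisq = w$chisq, df = w$df, p = w$p,
    random_intercept_var = x$varcomp$variance[x$varcomp$group ==
                                                "participant_id"],
    residual_var = x$varcomp$variance[x$varcomp$group == "Residual"],
    n_obs = x$n_obs, n_participants = x$n_participants
  )
}

regression_predictor_sets <- list(
  thermosensitivity = c("high_temp_sensitivity", "solitary_thermoregulation",
                        "social_thermoregulation", "heat_perception",
                        "heat_induced_warming"),
  sensibility = c("noticing", "not_distracting", "not_worrying",
                  "attention_regulation", "emotional_awareness",
                  "self_regulation", "body_listening", "trusting",
                  "body_awareness")
)

#' Exploratory regressions of thermal accuracy on questionnaire subscales
#'
#' Ordinary least squares of the thermal accuracy index on one of two
#' predictor sets: `"thermosensitivity"` (STRAQ-1 High Temperature
#' Sensitivity, Solitary and Social Thermoregulation; ETSRS Heat Perception
#' and Heat-Induced Warming) or `"sensibility"` (the eight MAIA-2 subscales
#' plus the BPQ-SF body-awareness score). Reports the coefficient table with
#' Bonferroni-adjusted p values across the predictor terms and a Type III
#' Wald chi-square per term.
#'
#' @param scores A data frame with one row per participant containing the
#'   outcome and predictor columns (see [subscales_wide()]).
#' @param model `"thermosensitivity"`, `"sensibility"`, or `"custom"` with
#'   `predictors` supplied.
#' @param dv Outcome column (default `"thermal_iacc"`).
#' @param predictors Character vector of predictor columns when
#'   `model = "custom"`.
#' @return An object of class `thermo_lm_fit`: list with `coefficients`
#'   (term, estimate, se, t, p, p_bonferroni), `wald` (Type III chi-square),
#'   `model` (the `lm`), `n`.
#' @export
fit_regressions <- function(scores,
                            model = c("thermosensitivity", "sensibility",
                                      "custom"),
                            dv = "thermal_iacc", predictors = NULL) {
  model <- match.arg(model)
  if (model != "custom") predictors <- regression_predictor_sets[[model]]
  if (is.null(predictors) || length(predictors) < 1) {
    abort("`predictors` must be supplied for a custom model.",
          class = "thermo_input_error")
  }
  need <- c(dv, predictors)
  if (!all(need %in% names(scores))) {
    abort(paste("Missing columns:",
                paste(setdiff(need, names(scores)), collapse = ", ")),
          class = "thermo_input_error")
  }
  d <- scores[complete.cases(scores[, need]), need, drop = FALSE]
  if (nrow(d) < length(predictors) + 2) {
    abort(sprintf("Need at least %d complete cases, have %d.",
                  length(predictors) + 2, nrow(d)),
          class = "thermo_input_error")
  }
  fml <- stats::reformulate(predictors, response = dv)
  fit <- lm(fml, data = d)
  aliased <- is.na(coef(fit))
  if (any(aliased)) {
    abort(paste("Rank-deficient design; collinear term(s):",
                paste(names(coef(fit))[aliased], collapse = ", ")),
          class = "thermo_collinear_error")
  }
  cf <- summary(fit)$coefficients
  is_pred <- rownames(cf) != "(Intercept)"
  coefs <- tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    se = unname(cf[, "Std. Error"]),
    t = unname(cf[, "t value"]),
    p = unname(cf[, "Pr(>|t|)"]),
    p_bonferroni = ifelse(is_pred,
                          pmin(1, unname(cf[, "Pr(>|t|)"]) * sum(is_pred)),
                          NA_real_)
  )
  wald <- tryCatch({
    aov <- car::Anova(fit, type = 3, test.statistic = "Chisq")
    keep <- !(rownames(aov) %in% c("Residuals"))
    tibble(term = rownames(aov)[keep], chisq = aov[["Chisq"]][keep],
           df = aov[["Df"]][keep], p = aov[["Pr(>Chisq)"]][keep])
  }, error = function(e) {
    # degenerate (e.g. zero-residual) fits have no Wald scale
    tibble(term = names(coef(fit)), chisq = NA_real_, df = 1,
           p = NA_real_)
  })
  structure(
    list(coefficients = coefs, wald = wald, model = fit, dv = dv,
         predictors = predictors, n = nrow(d)),
    class = "thermo_lm_fit"
  )
}

#' @export
print.thermo_lm_fit <- function(x, ...) {
  cat(sprintf("<regression: %s ~ %s>\n", x$dv,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  n = %d complete cases\n", x$n))
  print(x$coefficients)
  invisible(x)
}

#' @method tidy thermo_lm_fit
#' @export
tidy.thermo_lm_fit <- function(x, ...) x$coefficients

#' @method glance thermo_lm_fit
#' @export
glance.thermo_lm_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble(r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
         sigma = s$sigma, n = x$n, df_residual = s$df[2])
}
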