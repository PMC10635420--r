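#' Simulation configuration for a synthetic thermoception study
#'
#' Builds the parameter set that [simulate_study()] uses to generate a
#' complete synthetic dataset: thermal-trial temperature series, a
#' psychophysical observer producing perceived-change VAS ratings, end-of-task
#' confidence ratings, heartbeat-counting trials, and questionnaire item
#' responses. Defaults emulate the original validation study: 31 participants,
#' 15 thermal trials (3 per intensity level in randomized order), a mean
#' baseline hand temperature of 32.39 degC (SD 1.24), intensity-dependent mean
#' warming of roughly 0.05/0.65/1.49/2.11/2.35 degC for the 0/25/50/75/100%
#' levels, and four heartbeat-counting intervals of 25, 35, 45 and 100 s.
#'
#' @param n_participants Number of participants (default 31).
#' @param intensities Stimulation intensity levels in percent of maximum bulb
#'   power; strictly increasing (default `c(0, 25, 50, 75, 100)`).
#' @param trials_per_intensity Thermal trials per level (default 3).
#' @param baseline_temp_mean,baseline_temp_sd Baseline palm temperature
#'   distribution, degC (defaults 32.39 and 1.24).
#' @param delta_means Named vector mapping each intensity level to its mean
#'   true temperature change in degC.
#' @param delta_sd Between-trial SD of the true change, degC (default 0.35).
#' @param delta_participant_sd SD of a participant-level warming
#'   susceptibility shift added to every trial's mean change, degC (default
#'   0.15); reflects stable individual differences in skin thermal response
#'   and gives the mixed models a nonzero participant intercept variance.
#' @param stim_duration Stimulation duration in seconds (default 20).
#' @param sample_rate AOI sampling rate in Hz (default 1).
#' @param temp_noise_sd Per-sample camera noise SD, degC (default 0.02).
#' @param vas_gain_mean,vas_gain_sd Distribution of the observer's response
#'   gain on the standardized change scale (defaults 0.8 and 0.25).
#' @param vas_bias_mean,vas_bias_sd Distribution of the observer's additive
#'   response bias in VAS points (defaults 10 and 10).
#' @param vas_noise_sd Trial-level response noise SD in VAS points at the top
#'   of the standardized-change scale (default 25). The effective SD of a
#'   trial scales with stimulus magnitude (Weber-like):
#'   `vas_noise_sd * (vas_noise_floor + (1 - vas_noise_floor) * SHTC/100)`,
#'   so judgements of "no change" are made with much less scatter than
#'   judgements of large changes.
#' @param vas_noise_floor Fraction of `vas_noise_sd` that applies at zero
#'   standardized change (default 0.25).
#' @param confidence_bias,confidence_noise_sd Offset and SD of the end-of-task
#'   confidence rating around the participant's realized accuracy (defaults 5
#'   and 12 VAS points).
#' @param hct_intervals Heartbeat-counting interval durations in seconds
#'   (default `c(25, 35, 45, 100)`).
#' @param hr_mean,hr_sd Participant resting heart-rate distribution, beats/min
#'   (defaults 70 and 10).
#' @param hr_trial_sd Within-participant between-trial heart-rate SD,
#'   beats/min (default 2).
#' @param hct_attenuation_mean,hct_attenuation_sd Distribution of the fraction
#'   of recorded beats a participant perceives; draws are clipped to
#'   \[0, 1\] (defaults 0.5 and 0.3).
#' @param hct_count_noise_sd SD of the additive counting noise in beats
#'   (default 2).
#' @param questionnaire_effects Named numeric vector of subscale associations
#'   with latent thermal accuracy, in response-scale units per SD of accuracy;
#'   names are `"<instrument>:<subscale>"` as produced by
#'   [default_questionnaire_keys()]. Unnamed subscales get 0. Default: all 0.
#' @param questionnaire_noise_sd Participant-level subscale noise SD on the
#'   response scale (default 0.8).
#' @param seed Optional integer seed stored with the configuration and used
#'   by [simulate_study()] when no explicit seed is supplied.
#'
#' @return An object of class `thermo_sim_config` (a named list).
#' @seealso [simulate_study()], [simulate_questionnaires()]
#' @examples
#' cfg <- sim_config(n_participants = 4, seed = 1)
#' cfg$delta_means
#' @export
sim_config <- function(n_participants = 31,
                       intensities = c(0, 25, 50, 75, 100),
                       trials_per_intensity = 3,
                       baseline_temp_mean = 32.39,
                       baseline_temp_sd = 1.24,
                       delta_means = c(`0` = 0.05, `25` = 0.65, `50` = 1.49,
                                       `75` = 2.11, `100` = 2.35),
                       delta_sd = 0.35,
                       delta_participant_sd = 0.15,
                       stim_duration = 20,
                       sample_rate = 1,
                       temp_noise_sd = 0.02,
                       vas_gain_mean = 0.8,
                       vas_gain_sd = 0.25,
                       vas_bias_mean = 10,
                       vas_bias_sd = 10,
                       vas_noise_sd = 25,
                       vas_noise_floor = 0.25,
                       confidence_bias = 5,
                       confidence_noise_sd = 12,
                       hct_intervals = c(25, 35, 45, 100),
                       hr_mean = 70,
                       hr_sd = 10,
                       hr_trial_sd = 2,
                       hct_attenuation_mean = 0.5,
                       hct_attenuation_sd = 0.3,
                       hct_count_noise_sd = 2,
                       questionnaire_effects = NULL,
                       questionnaire_noise_sd = 0.8,
                       seed = NULL) {
  cfg <- list(
    n_participants = n_participants,
    intensities = intensities,
    trials_per_intensity = trials_per_intensity,
    baseline_temp_mean = baseline_temp_mean,
    baseline_temp_sd = baseline_temp_sd,
    delta_means = delta_means,
    delta_sd = delta_sd,
    delta_participant_sd = delta_participant_sd,
    stim_duration = stim_duration,
    sample_rate = sample_rate,
    temp_noise_sd = temp_noise_sd,
    vas_gain_mean = vas_gain_mean,
    vas_gain_sd = vas_gain_sd,
    vas_bias_mean = vas_bias_mean,
    vas_bias_sd = vas_bias_sd,
    vas_noise_sd = vas_noise_sd,
    vas_noise_floor = vas_noise_floor,
    confidence_bias = confidence_bias,
    confidence_noise_sd = confidence_noise_sd,
    hct_intervals = hct_intervals,
    hr_mean = hr_mean,
    hr_sd = hr_sd,
    hr_trial_sd = hr_trial_sd,
    hct_attenuation_mean = hct_attenuation_mean,
    hct_attenuation_sd = hct_attenuation_sd,
    hct_count_noise_sd = hct_count_noise_sd,
    questionnaire_effects = questionnaire_effects,
    questionnaire_noise_sd = questionnaire_noise_sd,
    seed = seed
  )
  class(cfg) <- "thermo_sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  bad <- function(field, msg) {
    abort(sprintf("Invalid simulation configuration: `%s` %s.", field, msg),
          class = "thermo_config_error")
  }
  chk_count <- function(field, min = 1) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
        x != floor(x)) {
      bad(field, sprintf("must be a single integer >= %d", min))
    }
  }
  chk_num <- function(field, min = -Inf, strict = FALSE) {
    x <- cfg[[field]]
    ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
      (if (strict) x > min else x >= min)
    if (!ok) {
      bad(field, sprintf("must be a finite number %s %s",
                         if (strict) ">" else ">=", format(min)))
    }
  }
  chk_count("n_participants")
  chk_count("trials_per_intensity")
  if (!is.numeric(cfg$intensities) || length(cfg$intensities) < 1 ||
      anyNA(cfg$intensities) || is.unsorted(cfg$intensities, strictly = TRUE)) {
    bad("intensities", "must be a strictly increasing numeric vector")
  }
  for (f in c("delta_sd", "delta_participant_sd", "baseline_temp_sd", "temp_noise_sd", "vas_gain_sd",
              "vas_bias_sd", "vas_noise_sd", "vas_noise_floor", "confidence_noise_sd", "hr_sd",
              "hr_trial_sd", "hct_attenuation_sd", "hct_count_noise_sd",
              "questionnaire_noise_sd")) {
    chk_num(f, min = 0)
  }
  chk_num("stim_duration", min = 0, strict = TRUE)
  chk_num("sample_rate", min = 0, strict = TRUE)
  dm <- cfg$delta_means
  if (is.null(names(dm)) ||
      !all(as.character(cfg$intensities) %in% names(dm))) {
    bad("delta_means", "must be a named vector covering every intensity level")
  }
  if (!is.numeric(cfg$hct_intervals) || length(cfg$hct_intervals) < 1 ||
      any(cfg$hct_intervals <= 0)) {
    bad("hct_intervals", "must be positive durations in seconds")
  }
  qe <- cfg$questionnaire_effects
  if (!is.null(qe) && (!is.numeric(qe) || is.null(names(qe)) || anyNA(qe))) {
    bad("questionnaire_effects",
        "must be a named numeric vector (\"instrument:subscale\" = effect)")
  }
  if (!is.null(cfg$seed)) {
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
        cfg$seed != floor(cfg$seed)) {
      bad("seed", "must be a single integer")
    }
  }
  cfg
}

#' @export
print.thermo_sim_config <- function(x, ...) {
  cat("<thermoception simulation config>\n")
  cat(sprintf("  %d participants x %d thermal trials (%d per intensity)\n",
              x$n_participants,
              x$trials_per_intensity * length(x$intensities),
              x$trials_per_intensity))
  cat("  intensities (%):", paste(x$intensities, collapse = ", "), "\n")
  cat("  mean delta-T (degC):",
      paste(sprintf("%s=%.2f", names(x$delta_means), x$delta_means),
            collapse = ", "), "\n")
  cat("  HCT intervals (s):", paste(x$hct_intervals, collapse = ", "), "\n")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' @param path File path of the YAML configuration.
#' @return `read_sim_config()` returns a `thermo_sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$delta_means)) raw$delta_means <- unlist(raw$delta_means)
  if (!is.null(raw$questionnaire_effects)) {
    raw$questionnaire_effects <- unlist(raw$questionnaire_effects)
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config A `thermo_sim_config` object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "thermo_sim_config"))
  out <- unclass(config)
  out$delta_means <- as.list(out$delta_means)
  if (!is.null(out$questionnaire_effects)) {
    out$questionnaire_effects <- as.list(out$questionnaire_effects)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}
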