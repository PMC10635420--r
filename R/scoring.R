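#' Standardized hand temperature change (SHTC) and per-trial accuracy
#'
#' For each participant the absolute real temperature change of every trial
#' is rescaled to 0-100 by the participant's largest absolute change across
#' *all* of their trials (baseline trials included):
#' `shtc = |real_delta| * 100 / max |real_delta|`. 0 means no change, 100 the
#' participant's largest change. When a `perceived_vas` column is present a
#' per-trial accuracy `trial_accuracy = 100 - |shtc - perceived_vas|` is
#' added as well.
#'
#' @param trials A data frame with columns `participant_id`, `real_delta`
#'   and optionally `perceived_vas`; one row per thermal trial.
#' @return The input tibble with an `shtc` column (and `trial_accuracy` when
#'   applicable) appended.
#' @details A participant whose trials all have `real_delta == 0` has no
#'   defined standardization (division by zero); this signals an unusable
#'   recording and raises an error of class `thermo_degenerate_error`.
#' @examples
#' trials <- tibble::tibble(
#'   participant_id = "p1",
#'   real_delta = c(0.2, 1, 2, 2.5),
#'   perceived_vas = c(10, 35, 85, 95)
#' )
#' standardize_changes(trials)
#' @export
standardize_changes <- function(trials) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0) {
    abort("`trials` is empty.", class = "thermo_input_error")
  }
  if (!all(c("participant_id", "real_delta") %in% names(trials))) {
    abort("`trials` needs columns participant_id and real_delta.",
          class = "thermo_input_error")
  }
  out <- trials %>%
    group_by(.data$participant_id) %>%
    mutate(.max_abs = max(abs(.data$real_delta), na.rm = TRUE)) %>%
    ungroup()
  degenerate <- out %>%
    filter(.data$.max_abs == 0) %>%
    pull("participant_id") %>%
    unique()
  if (length(degenerate) > 0) {
    abort(sprintf(
      "All real temperature changes are zero for participant(s) %s; SHTC is undefined.",
      paste(degenerate, collapse = ", ")),
      class = "thermo_degenerate_error")
  }
  out <- out %>%
    mutate(shtc = (abs(.data$real_delta) / .data$.max_abs) * 100) %>%
    select(-".max_abs")
  if ("perceived_vas" %in% names(out)) {
    out <- mutate(out,
                  trial_accuracy = 100 - abs(.data$shtc - .data$perceived_vas))
  }
  out
}

#' Thermal interoceptive accuracy
#'
#' Per-participant mean of `100 - |SHTC - perceived VAS|` over the included
#' trials. The headline index (default) uses only the active stimulation
#' trials (every level above the minimum), because accuracy at the no-change
#' baseline level reflects a different, easier judgement; the SHTC
#' standardization itself always uses all trials. Missing trials simply
#' reduce the trial count.
#'
#' @param trials A data frame with columns `participant_id`, `intensity`,
#'   `shtc`, `perceived_vas` (e.g. the output of [standardize_changes()]).
#' @param active_only Drop the lowest (baseline) intensity level
#'   (default `TRUE`).
#' @return A tibble with `participant_id`, `thermal_iacc`, `n_trials`.
#' @export
thermal_accuracy <- function(trials, active_only = TRUE) {
  stopifnot(is.data.frame(trials))
  need <- c("participant_id", "shtc", "perceived_vas")
  if (active_only) need <- c(need, "intensity")
  if (!all(need %in% names(trials))) {
    abort(paste("`trials` needs columns", paste(need, collapse = ", ")),
          class = "thermo_input_error")
  }
  use <- trials %>% filter(!is.na(.data$shtc), !is.na(.data$perceived_vas))
  if (active_only) {
    use <- filter(use, .data$intensity != min(trials$intensity, na.rm = TRUE))
  }
  if (nrow(use) == 0) {
    abort("No usable trials after subsetting.", class = "thermo_input_error")
  }
  use %>%
    group_by(.data$participant_id) %>%
    summarise(
      thermal_iacc = mean(100 - abs(.data$shtc - .data$perceived_vas)),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}

check_vas_range <- function(x, name) {
  if (any(!is.na(x) & (x < 0 | x > 100))) {
    abort(sprintf("`%s` must lie in [0, 100].", name),
          class = "thermo_input_error")
  }
}

#' Thermal interoceptive awareness
#'
#' Metacognitive calibration between the single end-of-task confidence
#' rating and the accuracy index:
#' `awareness = 100 - |confidence - accuracy|`. 100 means the participant's
#' confidence matches their measured accuracy exactly. The formula is
#' symmetric in its two arguments. Vectorized.
#'
#' @param confidence_vas End-of-task confidence rating(s), 0-100.
#' @param thermal_iacc Thermal accuracy index, 0-100.
#' @return Numeric awareness score(s) in \[0, 100\].
#' @examples
#' thermal_awareness(80, 73.07)
#' @export
thermal_awareness <- function(confidence_vas, thermal_iacc) {
  check_vas_range(confidence_vas, "confidence_vas")
  check_vas_range(thermal_iacc, "thermal_iacc")
  100 - abs(confidence_vas - thermal_iacc)
}

#' Cardiac interoceptive accuracy (heartbeat counting)
#'
#' The standard heartbeat-counting score: per-trial
#' `100 * (1 - |recorded - perceived| / recorded)`, averaged over trials.
#' 100 means perfect counting; counting nothing scores 0; over-counting by
#' more than twice the recorded beats goes negative unless `clip_at_zero` is
#' set.
#'
#' @param hct_trials A data frame with columns `participant_id`,
#'   `recorded_beats` (>= 1), `perceived_beats` (>= 0).
#' @param clip_at_zero Clip per-trial scores at 0 (default `FALSE`).
#' @return A tibble with `participant_id`, `cardiac_iacc`, `n_trials`.
#' @export
cardiac_accuracy <- function(hct_trials, clip_at_zero = FALSE) {
  stopifnot(is.data.frame(hct_trials))
  need <- c("participant_id", "recorded_beats", "perceived_beats")
  if (!all(need %in% names(hct_trials))) {
    abort(paste("`hct_trials` needs columns", paste(need, collapse = ", ")),
          class = "thermo_input_error")
  }
  use <- filter(hct_trials, !is.na(.data$recorded_beats),
                !is.na(.data$perceived_beats))
  if (nrow(use) == 0) {
    abort("No usable heartbeat-counting trials.", class = "thermo_input_error")
  }
  if (any(use$recorded_beats < 1)) {
    abort("`recorded_beats` must be >= 1 on every trial.",
          class = "thermo_input_error")
  }
  use %>%
    mutate(score = 100 * (1 - abs(.data$recorded_beats -
                                    .data$perceived_beats) /
                            .data$recorded_beats),
           score = if (clip_at_zero) pmax(.data$score, 0) else .data$score) %>%
    group_by(.data$participant_id) %>%
    summarise(cardiac_iacc = mean(.data$score), n_trials = dplyr::n(),
              .groups = "drop")
}

#' Cardiac interoceptive awareness
#'
#' Same calibration formula as [thermal_awareness()], but the accuracy input
#' is allowed outside \[0, 100\] (unclipped heartbeat-counting scores can go
#' negative), in which case awareness may also leave \[0, 100\].
#'
#' @param confidence_vas End-of-task confidence rating(s), 0-100.
#' @param cardiac_iacc Cardiac accuracy score(s).
#' @return Numeric awareness score(s).
#' @export
cardiac_awareness <- function(confidence_vas, cardiac_iacc) {
  check_vas_range(confidence_vas, "confidence_vas")
  100 - abs(confidence_vas - cardiac_iacc)
}

#' Participant-level interoception scores for a whole dataset
#'
#' Runs the full scoring chain on a dataset (a `thermo_sim`, `thermo_data`,
#' or plain list with `thermal_trials`, `hct_trials`, `confidence`): SHTC
#' standardization over all trials, thermal accuracy over active trials,
#' cardiac accuracy over the counting intervals, and both awareness indices
#' from the per-task confidence ratings.
#'
#' @param data A dataset list (see above).
#' @param active_only Passed to [thermal_accuracy()].
#' @param clip_at_zero Passed to [cardiac_accuracy()].
#' @return A tibble with one row per participant: `thermal_iacc`,
#'   `thermal_awareness`, `cardiac_iacc`, `cardiac_awareness`,
#'   `thermal_confidence_vas`, `cardiac_confidence_vas`, and the trial
#'   counts behind each index.
#' @examples
#' sim <- simulate_study(sim_config(n_participants = 4, seed = 2),
#'                       include_series = FALSE)
#' score_participants(sim)
#' @export
score_participants <- function(data, active_only = TRUE,
                               clip_at_zero = FALSE) {
  stopifnot(all(c("thermal_trials", "hct_trials", "confidence") %in%
                  names(data)))
  scored <- standardize_changes(data$thermal_trials)
  th <- thermal_accuracy(scored, active_only = active_only) %>%
    rename(n_thermal_trials = "n_trials")
  ca <- cardiac_accuracy(data$hct_trials, clip_at_zero = clip_at_zero) %>%
    rename(n_hct_trials = "n_trials")
  conf <- data$confidence %>%
    tidyr::pivot_wider(names_from = "task", values_from = "confidence_vas",
                       names_glue = "{task}_confidence_vas")
  th %>%
    left_join(ca, by = "participant_id") %>%
    left_join(conf, by = "participant_id") %>%
    mutate(
      thermal_awareness = thermal_awareness(.data$thermal_confidence_vas,
                                            .data$thermal_iacc),
      cardiac_awareness = cardiac_awareness(.data$cardiac_confidence_vas,
                                            .data$cardiac_iacc)
    ) %>%
    select("participant_id", "thermal_iacc", "thermal_awareness",
           "cardiac_iacc", "cardiac_awareness", "thermal_confidence_vas",
           "cardiac_confidence_vas", "n_thermal_trials", "n_hct_trials")
}
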