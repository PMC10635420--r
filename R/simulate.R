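# truncated-at-zero normal via inverse CDF (exact, vectorized)
rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(pmax(rep(mean, length.out = n), 0))
  lo <- pnorm(0, mean, sd)
  qnorm(runif(n, lo, 1), mean, sd)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

pid_label <- function(i, n) sprintf("p%0*d", max(2, nchar(n)), i)

#' Simulate a complete synthetic thermoception study
#'
#' Generates, for each simulated participant: per-trial latent temperature
#' changes (normal around the configured level means, truncated at zero for
#' active levels; the 0% level may drift slightly negative, as after a water
#' bath), AOI temperature series rising from a baseline draw toward
#' baseline + delta along an exponential saturating ramp, perceived-change VAS
#' ratings from a linear observer acting on the standardized change
#' (`perceived = clip(gain * SHTC + bias + noise, 0, 100)`), end-of-task
#' confidence ratings centred on the participant's realized accuracy,
#' heartbeat-counting trials with attenuated counting
#' (`perceived = round(clip(attenuation, 0, 1) * recorded + noise)`, floored
#' at 0), and questionnaire item responses (see [simulate_questionnaires()]).
#' Trial order is randomized within participant. The run is deterministic
#' given `seed`.
#'
#' The ground truth records, per trial, both the latent draw and the realized
#' first-to-last series difference (what a thermal camera would deliver); the
#' observer responds to the standardized realized change, so a noise-free
#' unit-gain observer reproduces SHTC exactly and scores accuracy 100.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @param include_series If `FALSE`, skip generating the per-sample AOI
#'   temperature series (the realized change then equals the latent change).
#'   Useful for large Monte-Carlo runs where only trial-level quantities are
#'   needed.
#' @param keys Questionnaire keys for [simulate_questionnaires()].
#' @return An object of class `thermo_sim`: a list with tibbles
#'   `thermal_trials` (participant_id, trial, intensity, real_delta,
#'   perceived_vas), `aoi_series` (participant_id, trial, time_s, temp_C; or
#'   `NULL`), `hct_trials` (participant_id, trial, duration_s, recorded_beats,
#'   perceived_beats), `confidence` (participant_id, task, confidence_vas),
#'   `questionnaire_items`, and `ground_truth` (list of `participants` and
#'   `trials` tibbles), plus the `config` and `seed` used.
#' @examples
#' sim <- simulate_study(sim_config(n_participants = 3, seed = 1))
#' sim$thermal_trials
#' @export
simulate_study <- function(config = sim_config(), seed = config$seed,
                           include_series = TRUE,
                           keys = default_questionnaire_keys()) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_participants
  levels <- config$intensities
  tpi <- config$trials_per_intensity
  n_trials <- tpi * length(levels)
  ids <- pid_label(seq_len(n), n)

  participants <- tibble(
    participant_id = ids,
    vas_gain = rnorm(n, config$vas_gain_mean, config$vas_gain_sd),
    vas_bias = rnorm(n, config$vas_bias_mean, config$vas_bias_sd),
    hr_bpm = rnorm(n, config$hr_mean, config$hr_sd),
    hct_attenuation = clip(rnorm(n, config$hct_attenuation_mean,
                                 config$hct_attenuation_sd), 0, 1),
    delta_shift = rnorm(n, 0, config$delta_participant_sd)
  )

  # randomized trial order per participant
  intensity <- unlist(lapply(seq_len(n), function(i) {
    sample(rep(levels, tpi))
  }))
  trials <- tibble(
    participant_id = rep(ids, each = n_trials),
    trial = rep(seq_len(n_trials), times = n),
    intensity = intensity
  )
  mu <- unname(config$delta_means[as.character(trials$intensity)]) +
    rep(participants$delta_shift, each = n_trials)
  delta_latent <- numeric(nrow(trials))
  base_level <- trials$intensity == min(levels)
  delta_latent[base_level] <- rnorm(sum(base_level), mu[base_level],
                                    config$delta_sd)
  delta_latent[!base_level] <- rtnorm0(sum(!base_level), mu[!base_level],
                                       config$delta_sd)
  trials$baseline_temp <- rnorm(nrow(trials), config$baseline_temp_mean,
                                config$baseline_temp_sd)
  trials$delta_latent <- delta_latent

  aoi_series <- NULL
  if (include_series) {
    times <- seq(0, config$stim_duration, by = 1 / config$sample_rate)
    L <- length(times)
    # saturating ramp normalized to reach exactly baseline + delta at the end
    ramp <- (1 - exp(-3 * times / config$stim_duration)) / (1 - exp(-3))
    nt <- nrow(trials)
    temp <- rep(trials$baseline_temp, each = L) +
      rep(trials$delta_latent, each = L) * rep(ramp, times = nt)
    noise <- rnorm(nt * L, 0, config$temp_noise_sd)
    # first/last samples are the measurement anchors and stay noise-free
    noise[rep(c(TRUE, rep(FALSE, L - 2), TRUE), times = nt)] <- 0
    aoi_series <- tibble(
      participant_id = rep(trials$participant_id, each = L),
      trial = rep(trials$trial, each = L),
      time_s = rep(times, times = nt),
      temp_C = temp + noise
    )
    # realized change is what the camera record delivers (here: exact)
    first_idx <- seq(1, nt * L, by = L)
    trials$delta_realized <- aoi_series$temp_C[first_idx + L - 1] -
      aoi_series$temp_C[first_idx]
  } else {
    trials$delta_realized <- trials$delta_latent
  }

  # observer: linear in the standardized realized change, clipped to the VAS
  trials <- trials %>%
    group_by(.data$participant_id) %>%
    mutate(shtc_true = (abs(.data$delta_realized) /
                          max(abs(.data$delta_realized))) * 100) %>%
    ungroup() %>%
    left_join(participants, by = "participant_id") %>%
    mutate(
      .noise_sd = config$vas_noise_sd *
        (config$vas_noise_floor +
           (1 - config$vas_noise_floor) * .data$shtc_true / 100),
      perceived_vas = clip(.data$vas_gain * .data$shtc_true +
                             .data$vas_bias +
                             rnorm(dplyr::n(), 0, 1) * .data$.noise_sd,
                           0, 100)
    ) %>%
    select(-".noise_sd")

  thermal_trials <- trials %>%
    select("participant_id", "trial", "intensity",
           real_delta = "delta_realized", "perceived_vas")

  # heartbeat counting task
  n_int <- length(config$hct_intervals)
  hct <- tibble(
    participant_id = rep(ids, each = n_int),
    trial = rep(seq_len(n_int), times = n),
    duration_s = rep(config$hct_intervals, times = n)
  ) %>%
    left_join(participants, by = "participant_id") %>%
    mutate(
      hr_trial = .data$hr_bpm + rnorm(dplyr::n(), 0, config$hr_trial_sd),
      recorded_beats = pmax(1, round(.data$hr_trial * .data$duration_s / 60)),
      perceived_beats = pmax(0, round(.data$hct_attenuation *
                                        .data$recorded_beats +
                                        rnorm(dplyr::n(), 0,
                                              config$hct_count_noise_sd)))
    )
  hct_trials <- hct %>%
    select("participant_id", "trial", "duration_s", "recorded_beats",
           "perceived_beats")

  # realized accuracies anchor the confidence ratings
  active <- trials$intensity != min(levels)
  thermal_iacc <- trials[active, ] %>%
    group_by(.data$participant_id) %>%
    summarise(acc = mean(100 - abs(.data$shtc_true - .data$perceived_vas)),
              .groups = "drop")
  cardiac_iacc <- hct %>%
    group_by(.data$participant_id) %>%
    summarise(acc = mean(100 * (1 - abs(.data$recorded_beats -
                                          .data$perceived_beats) /
                                  .data$recorded_beats)),
              .groups = "drop")
  confidence <- bind_rows(
    tibble(participant_id = thermal_iacc$participant_id, task = "thermal",
           anchor = thermal_iacc$acc),
    tibble(participant_id = cardiac_iacc$participant_id, task = "cardiac",
           anchor = cardiac_iacc$acc)
  ) %>%
    mutate(confidence_vas = clip(.data$anchor + config$confidence_bias +
                                   rnorm(dplyr::n(), 0,
                                         config$confidence_noise_sd),
                                 0, 100)) %>%
    select("participant_id", "task", "confidence_vas") %>%
    arrange(match(.data$task, c("thermal", "cardiac")), .data$participant_id)

  participants <- participants %>%
    left_join(rename(thermal_iacc, latent_accuracy = "acc"),
              by = "participant_id")

  questionnaire_items <- simulate_questionnaires(
    config, ground_truth = participants, keys = keys
  )

  structure(
    list(
      thermal_trials = thermal_trials,
      aoi_series = aoi_series,
      hct_trials = hct_trials,
      confidence = confidence,
      questionnaire_items = questionnaire_items,
      ground_truth = list(
        participants = participants,
        trials = trials %>% select("participant_id", "trial", "intensity",
                                   "baseline_temp", "delta_latent",
                                   "delta_realized", "shtc_true")
      ),
      config = config,
      seed = seed
    ),
    class = "thermo_sim"
  )
}

#' @export
print.thermo_sim <- function(x, ...) {
  cat("<synthetic thermoception study>\n")
  cat(sprintf("  %d participants, %d thermal trials each, %d HCT intervals\n",
              dplyr::n_distinct(x$thermal_trials$participant_id),
              max(x$thermal_trials$trial),
              length(x$config$hct_intervals)))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate questionnaire item responses tied to latent accuracy
#'
#' Draws item-level responses for every instrument in `keys`. Each
#' participant's subscale level is the scale midpoint plus
#' `effect * z(latent_accuracy)` plus normal noise
#' (`config$questionnaire_noise_sd`); items scatter around that level with a
#' fixed item noise (SD 0.7), are rounded to the nearest scale point and
#' clipped to the instrument's response range. With all effects zero
#' (the default) the questionnaires carry no information about accuracy.
#'
#' @inheritParams simulate_study
#' @param ground_truth A data frame with columns `participant_id` and
#'   `latent_accuracy` (e.g. `sim$ground_truth$participants`).
#' @return A long tibble: `participant_id`, `instrument`, `item`, `response`.
#' @export
simulate_questionnaires <- function(config, ground_truth,
                                    keys = default_questionnaire_keys()) {
  stopifnot(is.data.frame(ground_truth),
            all(c("participant_id", "latent_accuracy") %in%
                  names(ground_truth)))
  acc <- ground_truth$latent_accuracy
  z <- if (sd(acc) > 0) (acc - mean(acc)) / sd(acc) else rep(0, length(acc))
  effects <- config$questionnaire_effects %||% numeric()
  kt <- key_table(keys)
  sub_tab <- kt %>% dplyr::distinct(.data$instrument, .data$subscale,
                                    .data$lo, .data$hi)
  n <- length(acc)
  item_noise_sd <- 0.7

  out <- purrr::map_dfr(seq_len(nrow(sub_tab)), function(i) {
    ins <- sub_tab$instrument[i]; sub <- sub_tab$subscale[i]
    lo <- sub_tab$lo[i]; hi <- sub_tab$hi[i]
    beta <- unname(effects[paste0(ins, ":", sub)])
    if (length(beta) == 0 || is.na(beta)) beta <- 0
    items <- kt$item[kt$instrument == ins & kt$subscale == sub]
    latent <- (lo + hi) / 2 + beta * z +
      rnorm(n, 0, config$questionnaire_noise_sd)
    k <- length(items)
    resp <- clip(round(rep(latent, each = k) +
                         rnorm(n * k, 0, item_noise_sd)), lo, hi)
    tibble(
      participant_id = rep(ground_truth$participant_id, each = k),
      instrument = ins,
      item = rep(items, times = n),
      response = resp
    )
  })
  arrange(out, .data$participant_id, .data$instrument, .data$item)
}

#' Write a synthetic dataset as a file tree of plain-text tables
#'
#' Emits one FLIR-style AOI CSV per thermal trial (columns `time_s`,
#' `temp_C`) under `aoi/`, plus tidy tables `thermal_trials.csv`,
#' `hct_trials.csv`, `confidence.csv`, `questionnaire_items.csv`, and the
#' generating configuration as `sim_config.yaml`. The tree round-trips
#' through [read_dataset()].
#'
#' @param sim A `thermo_sim` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "thermo_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sim$thermal_trials, file.path(dir, "thermal_trials.csv"))
  readr::write_csv(sim$hct_trials, file.path(dir, "hct_trials.csv"))
  readr::write_csv(sim$confidence, file.path(dir, "confidence.csv"))
  readr::write_csv(sim$questionnaire_items,
                   file.path(dir, "questionnaire_items.csv"))
  write_sim_config(sim$config, file.path(dir, "sim_config.yaml"))
  if (!is.null(sim$seed)) {
    writeLines(as.character(sim$seed), file.path(dir, "seed.txt"))
  }
  if (!is.null(sim$aoi_series)) {
    aoi_dir <- file.path(dir, "aoi")
    dir.create(aoi_dir, showWarnings = FALSE)
    split_keys <- split(
      sim$aoi_series,
      list(sim$aoi_series$participant_id, sim$aoi_series$trial),
      drop = TRUE
    )
    for (chunk in split_keys) {
      fn <- sprintf("%s_trial%02d.csv", chunk$participant_id[1],
                    chunk$trial[1])
      readr::write_csv(chunk[, c("time_s", "temp_C")],
                       file.path(aoi_dir, fn))
    }
  }
  invisible(dir)
}

#' Read a dataset file tree back into trial tables
#'
#' Reads the tidy tables written by [write_dataset()] (or an equivalently
#' arranged export of a real study). If an `aoi/` directory of per-trial CSVs
#' is present, per-trial real temperature changes are recomputed from the
#' series via [real_change()] and override any `real_delta` column in
#' `thermal_trials.csv`.
#'
#' @param dir Directory containing the dataset.
#' @return A list with `thermal_trials`, `hct_trials`, `confidence`,
#'   `questionnaire_items` tibbles (class `thermo_data`).
#' @export
read_dataset <- function(dir) {
  need <- file.path(dir, "thermal_trials.csv")
  if (!file.exists(need)) {
    abort(sprintf("No `thermal_trials.csv` under %s.", dir),
          class = "thermo_io_error")
  }
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) readr::read_csv(p, show_col_types = FALSE) else NULL
  }
  thermal <- rd("thermal_trials.csv")
  aoi_dir <- file.path(dir, "aoi")
  if (dir.exists(aoi_dir)) {
    files <- list.files(aoi_dir, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) > 0) {
      deltas <- purrr::map_dfr(files, function(f) {
        m <- regmatches(basename(f),
                        regexec("^(.*)_trial([0-9]+)\\.csv$", basename(f)))[[1]]
        series <- read_aoi_csv(f)
        rc <- real_change(series)
        tibble(participant_id = m[2], trial = as.integer(m[3]),
               real_delta = rc$delta)
      })
      thermal <- thermal %>%
        select(-dplyr::any_of("real_delta")) %>%
        left_join(deltas, by = c("participant_id", "trial"))
    }
  }
  structure(
    list(
      thermal_trials = thermal,
      hct_trials = rd("hct_trials.csv"),
      confidence = rd("confidence.csv"),
      questionnaire_items = rd("questionnaire_items.csv")
    ),
    class = "thermo_data"
  )
}
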