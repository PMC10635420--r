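#' Run the full analysis pipeline
#'
#' Orchestrates the complete reproduction: obtain a dataset (simulate one, or
#' ingest a file tree written by [write_dataset()] or arranged like it),
#' score every trial and participant, and run the enabled analyses:
#' \describe{
#'   \item{descriptives}{mean, SD, min, max of each interoception index.}
#'   \item{reliability}{Cronbach's alpha of thermal accuracy across active
#'     intensity levels and of the heartbeat-counting score across
#'     intervals.}
#'   \item{intensity}{random-intercept mixed models of real change, perceived
#'     change and trial accuracy on stimulation intensity, with Type III
#'     Wald tests and Bonferroni pairwise contrasts.}
#'   \item{comparison}{paired t tests between modalities (cardiac minus
#'     thermal) and the four Bonferroni-corrected Pearson correlations with
#'     default Bayes factors.}
#'   \item{regressions}{the two exploratory questionnaire models
#'     (thermosensitivity; interoceptive sensibility).}
#' }
#' The run is deterministic given `seed` and the inputs.
#'
#' @param config A [sim_config()] (used in simulate mode).
#' @param seed Integer seed for simulate mode.
#' @param mode `"simulate"` or `"ingest"`.
#' @param input_dir Dataset directory for ingest mode.
#' @param analyses Character vector of analysis blocks to run.
#' @param active_only Use only active-intensity trials for the headline
#'   thermal index (default `TRUE`).
#' @param keys Questionnaire keys for subscale scoring.
#' @return An object of class `thermo_report`: a list with `tables` (named
#'   tibbles, one per enabled analysis plus `provenance`), `participant_scores`,
#'   `scored_trials`, `config`, `seed`.
#' @examples
#' rep <- run_study(sim_config(n_participants = 8), seed = 7,
#'                  analyses = c("descriptives", "comparison"))
#' rep$tables$descriptives
#' @export
run_study <- function(config = sim_config(), seed = NULL,
                      mode = c("simulate", "ingest"), input_dir = NULL,
                      analyses = c("descriptives", "reliability", "intensity",
                                   "comparison", "regressions"),
                      active_only = TRUE,
                      keys = default_questionnaire_keys()) {
  mode <- match.arg(mode)
  if (length(analyses) > 0) {
    analyses <- match.arg(analyses, several.ok = TRUE,
                          choices = c("descriptives", "reliability",
                                      "intensity", "comparison",
                                      "regressions"))
  }
  if (mode == "simulate") {
    data <- simulate_study(config, seed = seed %||% config$seed,
                           include_series = FALSE, keys = keys)
  } else {
    if (is.null(input_dir)) {
      abort("`input_dir` is required in ingest mode.",
            class = "thermo_config_error")
    }
    data <- read_dataset(input_dir)
  }

  scored <- standardize_changes(data$thermal_trials)
  scores <- score_participants(data, active_only = active_only)

  tables <- list()

  if ("descriptives" %in% analyses) {
    tables$descriptives <- scores %>%
      select("thermal_iacc", "thermal_awareness", "cardiac_iacc",
             "cardiac_awareness") %>%
      tidyr::pivot_longer(dplyr::everything(), names_to = "index") %>%
      group_by(.data$index) %>%
      summarise(mean = mean(.data$value), sd = sd(.data$value),
                min = min(.data$value), max = max(.data$value),
                n = dplyr::n(), .groups = "drop")
  }

  if ("reliability" %in% analyses) {
    thermal_items <- scored %>%
      filter(.data$intensity != min(.data$intensity)) %>%
      group_by(.data$participant_id, .data$intensity) %>%
      summarise(acc = mean(.data$trial_accuracy), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "intensity", values_from = "acc") %>%
      select(-"participant_id")
    cardiac_items <- data$hct_trials %>%
      mutate(score = 100 * (1 - abs(.data$recorded_beats -
                                      .data$perceived_beats) /
                              .data$recorded_beats)) %>%
      select("participant_id", "duration_s", "score") %>%
      tidyr::pivot_wider(names_from = "duration_s", values_from = "score") %>%
      select(-"participant_id")
    tables$reliability <- bind_rows(
      mutate(cronbach_alpha(thermal_items), index = "thermal_iacc",
             .before = 1),
      mutate(cronbach_alpha(cardiac_items), index = "cardiac_iacc",
             .before = 1)
    )
  }

  if ("intensity" %in% analyses) {
    dvs <- c(real_change = "real_delta", perceived_change = "perceived_vas",
             trial_accuracy = "trial_accuracy")
    fits <- purrr::imap(dvs, function(dv, label) {
      fit_intensity_model(scored, dv)
    })
    tables$intensity_wald <- purrr::imap_dfr(fits, function(f, label) {
      mutate(glance(f), analysis = label, .before = 1)
    })
    tables$intensity_contrasts <- purrr::imap_dfr(fits, function(f, label) {
      mutate(f$contrasts, analysis = label, .before = 1)
    })
    tables$intensity_emmeans <- purrr::imap_dfr(fits, function(f, label) {
      mutate(f$emmeans, analysis = label, .before = 1)
    })
  }

  if ("comparison" %in% analyses) {
    tables$comparison_ttests <- bind_rows(
      mutate(paired_ttest(scores$cardiac_iacc, scores$thermal_iacc),
             comparison = "accuracy_cardiac_minus_thermal", .before = 1),
      mutate(paired_ttest(scores$cardiac_awareness, scores$thermal_awareness),
             comparison = "awareness_cardiac_minus_thermal", .before = 1)
    )
    tables$comparison_correlations <- pearson_with_bonferroni(
      scores,
      pairs = list(
        c("thermal_iacc", "thermal_awareness"),
        c("cardiac_iacc", "cardiac_awareness"),
        c("thermal_iacc", "cardiac_iacc"),
        c("thermal_awareness", "cardiac_awareness")
      )
    )
  }

  if ("regressions" %in% analyses) {
    if (is.null(data$questionnaire_items) ||
        nrow(data$questionnaire_items) == 0) {
      abort("Regressions requested but no questionnaire items present.",
            class = "thermo_config_error")
    }
    wide <- score_subscales(data$questionnaire_items, keys = keys) %>%
      subscales_wide() %>%
      left_join(select(scores, "participant_id", "thermal_iacc"),
                by = "participant_id")
    fit1 <- fit_regressions(wide, "thermosensitivity")
    fit2 <- fit_regressions(wide, "sensibility")
    tables$regression_coefficients <- bind_rows(
      mutate(tidy(fit1), model = "thermosensitivity", .before = 1),
      mutate(tidy(fit2), model = "sensibility", .before = 1)
    )
    tables$regression_wald <- bind_rows(
      mutate(fit1$wald, model = "thermosensitivity", .before = 1),
      mutate(fit2$wald, model = "sensibility", .before = 1)
    )
  }

  cfg_for_hash <- if (mode == "simulate") unclass(config) else
    list(mode = "ingest", input_dir = normalizePath(input_dir))
  tables$provenance <- tibble(
    key = c("package_version", "r_version", "mode", "seed", "config_hash",
            "analyses"),
    value = c(as.character(packageVersion("thermoception")),
              paste(R.version$major, R.version$minor, sep = "."),
              mode,
              as.character(seed %||% config$seed %||% NA),
              rlang::hash(cfg_for_hash),
              paste(analyses, collapse = ","))
  )

  structure(
    list(tables = tables, participant_scores = scores,
         scored_trials = scored, data = data, config = config,
         seed = seed %||% config$seed),
    class = "thermo_report"
  )
}

#' @export
print.thermo_report <- function(x, ...) {
  cat("<thermoception analysis report>\n")
  cat("  tables:", paste(names(x$tables), collapse = ", "), "\n")
  cat(sprintf("  %d participants scored\n", nrow(x$participant_scores)))
  invisible(x)
}

#' @method tidy thermo_report
#' @export
tidy.thermo_report <- function(x, table = "descriptives", ...) {
  if (!table %in% names(x$tables)) {
    abort(sprintf("No table `%s` in report; available: %s.", table,
                  paste(names(x$tables), collapse = ", ")),
          class = "thermo_input_error")
  }
  x$tables[[table]]
}

#' @method glance thermo_report
#' @export
glance.thermo_report <- function(x, ...) {
  tibble(
    n_participants = nrow(x$participant_scores),
    n_tables = length(x$tables),
    mean_thermal_iacc = mean(x$participant_scores$thermal_iacc),
    mean_cardiac_iacc = mean(x$participant_scores$cardiac_iacc),
    seed = x$seed %||% NA_integer_
  )
}

#' Render a report to files
#'
#' Writes every report table as CSV (`<table>.csv` plus
#' `participant_scores.csv`), and optionally one figure per enabled plotting
#' target.
#'
#' @param report A `thermo_report`.
#' @param dir Output directory (created if absent).
#' @param format Output format; only `"csv"` is supported for tables.
#' @param plots Also write figures (default `FALSE`).
#' @return Invisibly, the vector of files written.
#' @export
render_report <- function(report, dir, format = "csv", plots = FALSE) {
  stopifnot(inherits(report, "thermo_report"))
  if (!identical(format, "csv")) {
    abort(sprintf("Unsupported format `%s`; only \"csv\" is available.",
                  format), class = "thermo_config_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(report$tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(report$tables[[nm]], f)
    files <- c(files, f)
  }
  f <- file.path(dir, "participant_scores.csv")
  readr::write_csv(report$participant_scores, f)
  files <- c(files, f)
  if (plots) {
    if (!is.null(report$scored_trials)) {
      f <- file.path(dir, "intensity_effects.pdf")
      ggplot2::ggsave(f, plot_intensity_effects(report$scored_trials),
                      width = 9, height = 4)
      files <- c(files, f)
    }
    f <- file.path(dir, "modality_comparison.pdf")
    ggplot2::ggsave(f, plot_modality_comparison(report$participant_scores),
                    width = 7, height = 5)
    files <- c(files, f)
  }
  invisible(files)
}
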