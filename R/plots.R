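#' Per-intensity boxplots of real change, perceived change and accuracy
#'
#' Mirrors the standard presentation of the stimulation-intensity effect:
#' one panel each for the real hand temperature change (degC), the perceived
#' change (VAS) and the per-trial accuracy, with one box per intensity level.
#'
#' @param scored_trials Output of [standardize_changes()] (needs
#'   `real_delta`, `perceived_vas`, `trial_accuracy`, `intensity`).
#' @return A ggplot object.
#' @export
plot_intensity_effects <- function(scored_trials) {
  long <- scored_trials %>%
    select("intensity", `real change (degC)` = "real_delta",
           `perceived change (VAS)` = "perceived_vas",
           `trial accuracy` = "trial_accuracy") %>%
    tidyr::pivot_longer(-"intensity", names_to = "measure") %>%
    mutate(intensity = factor(.data$intensity,
                              levels = sort(unique(.data$intensity))))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$intensity, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "stimulation intensity (% of maximum)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Distribution plots comparing the two interoceptive modalities
#'
#' Violin-and-box display of the participant-level accuracy and awareness
#' indices for the thermal and cardiac tasks.
#'
#' @param scores Output of [score_participants()].
#' @return A ggplot object.
#' @export
plot_modality_comparison <- function(scores) {
  long <- scores %>%
    select("participant_id", "thermal_iacc", "cardiac_iacc",
           "thermal_awareness", "cardiac_awareness") %>%
    tidyr::pivot_longer(-"participant_id",
                        names_to = c("modality", "index"),
                        names_pattern = "(thermal|cardiac)_(.*)") %>%
    mutate(index = ifelse(.data$index == "iacc", "accuracy", .data$index))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$modality, y = .data$value,
                                     fill = .data$modality)) +
    ggplot2::geom_violin(alpha = 0.4, colour = NA) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.6) +
    ggplot2::facet_wrap(~index) +
    ggplot2::labs(x = NULL, y = "score (0-100)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot thermo_report
#' @export
autoplot.thermo_report <- function(object, which = c("intensity", "modality"),
                                   ...) {
  which <- match.arg(which)
  if (which == "intensity") {
    plot_intensity_effects(object$scored_trials)
  } else {
    plot_modality_comparison(object$participant_scores)
  }
}
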