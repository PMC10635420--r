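#' Default questionnaire scoring keys
#'
#' Loads the item-to-subscale map for the four self-report instruments used in
#' the validation analyses: the ETSRS (Heat-Induced Warming, Heat Perception;
#' 1-7 response scale), the STRAQ-1 (High Temperature Sensitivity, Solitary
#' Thermoregulation, Social Thermoregulation; 1-5), the MAIA-2 (eight
#' subscales, 37 items; 0-5), and the BPQ-SF (22 items scored as one
#' body-awareness scale; 1-5). Keys live in an editable YAML file; pass your
#' own `path` to substitute study-specific item identifiers or reverse-coded
#' items.
#'
#' @param path Optional path to a YAML key file with the same structure as
#'   the packaged default.
#' @return A named list, one element per instrument, each with `range`
#'   (length-2 numeric), `reverse` (character vector of item ids) and
#'   `subscales` (named list of item-id character vectors).
#' @export
default_questionnaire_keys <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "questionnaire_keys.yaml",
                        package = "thermoception", mustWork = TRUE)
  }
  keys <- yaml::read_yaml(path)
  for (ins in names(keys)) {
    keys[[ins]]$range <- as.numeric(keys[[ins]]$range)
    keys[[ins]]$reverse <- as.character(keys[[ins]]$reverse %||% character())
    keys[[ins]]$subscales <- lapply(keys[[ins]]$subscales, as.character)
  }
  keys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flat lookup: one row per keyed item
key_table <- function(keys) {
  purrr::map_dfr(names(keys), function(ins) {
    purrr::map_dfr(names(keys[[ins]]$subscales), function(sub) {
      tibble(instrument = ins, subscale = sub,
             item = keys[[ins]]$subscales[[sub]],
             lo = keys[[ins]]$range[1], hi = keys[[ins]]$range[2],
             reverse = keys[[ins]]$subscales[[sub]] %in% keys[[ins]]$reverse)
    })
  })
}

#' Score questionnaire subscales from item-level responses
#'
#' Computes each subscale as the mean of its constituent items on the
#' instrument's own response scale, after un-reversing any reverse-coded
#' items. Responses are validated against the instrument range and the key.
#'
#' @param items A data frame with columns `participant_id`, `instrument`,
#'   `item`, `response` (long format, one row per answered item).
#' @param keys A key list as returned by [default_questionnaire_keys()].
#' @param missing Policy for items in the key but absent for a participant:
#'   `"error"` (default) fails; `"available"` averages the items that are
#'   present, requiring at least `min_coverage` of the subscale's items.
#' @param min_coverage Minimum fraction of a subscale's items that must be
#'   present under `missing = "available"` (default 0.5).
#' @return A tibble with columns `participant_id`, `instrument`, `subscale`,
#'   `score`, `n_items`.
#' @examples
#' keys <- default_questionnaire_keys()
#' items <- tibble::tibble(
#'   participant_id = "p1", instrument = "maia2",
#'   item = keys$maia2$subscales$self_regulation, response = 5
#' )
#' score_subscales(items, keys)
#' @export
score_subscales <- function(items, keys = default_questionnaire_keys(),
                            missing = c("error", "available"),
                            min_coverage = 0.5) {
  missing <- match.arg(missing)
  stopifnot(is.data.frame(items))
  req <- c("participant_id", "instrument", "item", "response")
  if (!all(req %in% names(items))) {
    abort(paste("`items` must have columns", paste(req, collapse = ", ")),
          class = "thermo_input_error")
  }
  kt <- key_table(keys)
  unknown <- setdiff(unique(items$item), kt$item)
  if (length(unknown) > 0) {
    abort(paste0("Unknown item id(s): ", paste(head(unknown, 5), collapse = ", "),
                 if (length(unknown) > 5) ", ..."),
          class = "thermo_input_error")
  }
  scored_items <- items %>%
    select("participant_id", "item", "response") %>%
    left_join(kt, by = "item")
  oob <- scored_items$response < scored_items$lo |
    scored_items$response > scored_items$hi | is.na(scored_items$response)
  if (any(oob)) {
    first <- which(oob)[1]
    abort(sprintf(
      "Out-of-range response for item `%s` (participant %s): %s not in [%g, %g].",
      scored_items$item[first], scored_items$participant_id[first],
      format(scored_items$response[first]), scored_items$lo[first],
      scored_items$hi[first]), class = "thermo_input_error")
  }
  scored_items <- scored_items %>%
    mutate(response = ifelse(.data$reverse,
                             .data$lo + .data$hi - .data$response,
                             .data$response))

  k_items <- kt %>% dplyr::count(.data$instrument, .data$subscale,
                                 name = "k_total")
  out <- scored_items %>%
    group_by(.data$participant_id, .data$instrument, .data$subscale) %>%
    summarise(score = mean(.data$response), n_items = dplyr::n(),
              .groups = "drop") %>%
    left_join(k_items, by = c("instrument", "subscale"))
  incomplete <- out$n_items < out$k_total
  if (any(incomplete)) {
    if (missing == "error") {
      first <- which(incomplete)[1]
      abort(sprintf(
        "Participant %s answered %d/%d items of %s:%s (missing = \"error\").",
        out$participant_id[first], out$n_items[first], out$k_total[first],
        out$instrument[first], out$subscale[first]),
        class = "thermo_missing_error")
    }
    low <- out$n_items / out$k_total < min_coverage
    if (any(low)) {
      first <- which(low)[1]
      abort(sprintf(
        "Participant %s covers only %d/%d items of %s:%s (< min_coverage).",
        out$participant_id[first], out$n_items[first], out$k_total[first],
        out$instrument[first], out$subscale[first]),
        class = "thermo_missing_error")
    }
  }
  out %>% select(-"k_total") %>% arrange(.data$participant_id,
                                         .data$instrument, .data$subscale)
}

#' Pivot subscale scores to one column per subscale
#'
#' Convenience reshaping for the regression models: one row per participant,
#' one column per subscale (subscale ids are unique across instruments).
#'
#' @param subscales Output of [score_subscales()].
#' @return A wide tibble keyed by `participant_id`.
#' @export
subscales_wide <- function(subscales) {
  subscales %>%
    select("participant_id", "subscale", "score") %>%
    tidyr::pivot_wider(names_from = "subscale", values_from = "score")
}
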