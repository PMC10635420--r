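trial_df <- function(deltas, perceived = NULL, intensity = NULL,
                     id = "p1") {
  out <- tibble::tibble(participant_id = id, real_delta = deltas)
  if (!is.null(perceived)) out$perceived_vas <- perceived
  if (!is.null(intensity)) out$intensity <- intensity
  out
}

test_that("SHTC rescales absolute changes by the participant's maximum", {
  got <- standardize_changes(trial_df(c(0.2, 1, 2, 2.5)))
  expect_equal(got$shtc, c(8, 40, 80, 100))

  # sign is dropped; ties at the maximum are allowed
  got <- standardize_changes(trial_df(c(-0.5, 0.5)))
  expect_equal(got$shtc, c(100, 100))

  # invariant under uniform positive rescaling of all deltas
  base <- standardize_changes(trial_df(c(0.1, 0.7, 1.3, 2)))
  scaled <- standardize_changes(trial_df(3 * c(0.1, 0.7, 1.3, 2)))
  expect_equal(base$shtc, scaled$shtc)

  # standardization is within participant
  two <- standardize_changes(dplyr::bind_rows(
    trial_df(c(1, 2), id = "a"), trial_df(c(2, 8), id = "b")))
  expect_equal(two$shtc, c(50, 100, 25, 100))

  expect_error(standardize_changes(trial_df(numeric())),
               class = "thermo_input_error")
  expect_error(standardize_changes(trial_df(c(0, 0, 0))),
               class = "thermo_degenerate_error")
})

test_that("thermal accuracy averages 100 minus the SHTC/VAS mismatch", {
  d <- trial_df(c(0.5, 1, 2), intensity = c(25, 50, 75))
  d$shtc <- c(20, 60, 90)
  d$perceived_vas <- c(30, 50, 100)
  expect_equal(thermal_accuracy(d, active_only = FALSE)$thermal_iacc, 90)

  d$perceived_vas <- d$shtc
  expect_equal(thermal_accuracy(d, active_only = FALSE)$thermal_iacc, 100)

  worst <- trial_df(c(1, 2), intensity = c(25, 50))
  worst$shtc <- c(0, 100); worst$perceived_vas <- c(100, 0)
  expect_equal(thermal_accuracy(worst, active_only = FALSE)$thermal_iacc, 0)

  # the headline index excludes the baseline level but keeps its SHTC anchor
  full <- standardize_changes(trial_df(
    c(0.1, 1, 2), perceived = c(90, 50, 100), intensity = c(0, 25, 50)))
  act <- thermal_accuracy(full, active_only = TRUE)
  expect_equal(act$n_trials, 2)
  expect_equal(act$thermal_iacc, mean(100 - abs(c(50, 100) - c(50, 100))))

  # missing trials reduce N instead of being imputed
  full$perceived_vas[2] <- NA
  expect_equal(thermal_accuracy(full, active_only = TRUE)$n_trials, 1)
})

test_that("awareness is the confidence-accuracy calibration", {
  expect_equal(thermal_awareness(80, 80), 100)
  expect_equal(thermal_awareness(100, 0), 0)
  expect_equal(thermal_awareness(80, 73.07), 93.07)
  expect_equal(thermal_awareness(73.07, 80), thermal_awareness(80, 73.07))
  expect_error(thermal_awareness(120, 50), class = "thermo_input_error")
  expect_error(thermal_awareness(50, -2), class = "thermo_input_error")

  expect_equal(cardiac_awareness(50, 50), 100)
  expect_equal(cardiac_awareness(0, 97.8), 2.2)
  # the cardiac formula extends below zero accuracy
  expect_equal(cardiac_awareness(60, -10), 30)
})

test_that("cardiac accuracy is the standard heartbeat-counting score", {
  hct <- tibble::tibble(
    participant_id = "p1",
    recorded_beats = c(30, 42, 54, 120),
    perceived_beats = c(30, 42, 54, 120)
  )
  expect_equal(cardiac_accuracy(hct)$cardiac_iacc, 100)

  hct$perceived_beats <- c(15, 21, 27, 60)  # half of recorded on each trial
  expect_equal(cardiac_accuracy(hct)$cardiac_iacc, 50)

  hct$perceived_beats <- 0
  expect_equal(cardiac_accuracy(hct)$cardiac_iacc, 0)

  # drastic over-counting goes negative unless clipped
  hct$perceived_beats <- hct$recorded_beats * 3
  expect_equal(cardiac_accuracy(hct)$cardiac_iacc, -100)
  expect_equal(cardiac_accuracy(hct, clip_at_zero = TRUE)$cardiac_iacc, 0)

  hct$recorded_beats[1] <- 0
  expect_error(cardiac_accuracy(hct), class = "thermo_input_error")
})

test_that("cardiac accuracy decreases strictly with the counting error", {
  rec <- c(30, 40, 50, 110)
  accs <- vapply(0:5, function(err) {
    cardiac_accuracy(tibble::tibble(
      participant_id = "p", recorded_beats = rec,
      perceived_beats = rec - err))$cardiac_iacc
  }, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("subscale scoring averages items and enforces the key", {
  keys <- default_questionnaire_keys()
  sr_items <- keys$maia2$subscales$self_regulation
  items <- tibble::tibble(participant_id = "p1", instrument = "maia2",
                          item = sr_items, response = 5)
  got <- score_subscales(items, keys)
  expect_equal(got$score, 5)

  hp <- tibble::tibble(participant_id = "p1", instrument = "etsrs",
                       item = keys$etsrs$subscales$heat_perception,
                       response = 1:7)
  expect_equal(score_subscales(hp, keys)$score, 4)

  expect_error(score_subscales(items[-1, ], keys),
               class = "thermo_missing_error")
  expect_equal(
    score_subscales(items[-1, ], keys, missing = "available")$n_items, 3)

  bad <- items; bad$response[1] <- 9
  expect_error(score_subscales(bad, keys), class = "thermo_input_error")
  unk <- items; unk$item[1] <- "mystery_item"
  expect_error(score_subscales(unk, keys), class = "thermo_input_error")
})

test_that("reverse-coded items are flipped before averaging", {
  keys <- default_questionnaire_keys()
  keys$maia2$reverse <- keys$maia2$subscales$not_distracting[1]
  nd <- keys$maia2$subscales$not_distracting
  items <- tibble::tibble(participant_id = "p1", instrument = "maia2",
                          item = nd, response = c(5, rep(2, 5)))
  got <- score_subscales(items, keys)
  expect_equal(got$score, mean(c(0 + 5 - 5, rep(2, 5))))
})

test_that("thermal indices stay in [0, 100] over random inputs", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:20, 1)
    d <- trial_df(rnorm(n, 1, 1), perceived = runif(n, 0, 100),
                  intensity = sample(c(0, 25, 50, 75, 100), n, replace = TRUE))
    sc <- standardize_changes(d)
    expect_true(all(sc$shtc >= 0 & sc$shtc <= 100))
    expect_true(all(sc$trial_accuracy >= 0 & sc$trial_accuracy <= 100))
    acc <- thermal_accuracy(sc, active_only = FALSE)$thermal_iacc
    expect_true(acc >= 0 && acc <= 100)
    conf <- runif(1, 0, 100)
    aw <- thermal_awareness(conf, acc)
    expect_true(aw >= 0 && aw <= 100)
  }
})

test_that("score_participants assembles all indices for a simulated study", {
  sim <- tiny_sim(n = 6, seed = 11)
  sc <- score_participants(sim)
  expect_equal(nrow(sc), 6)
  expect_equal(sc$n_thermal_trials, rep(12, 6))
  expect_equal(sc$n_hct_trials, rep(4, 6))
  expect_true(all(sc$thermal_iacc >= 0 & sc$thermal_iacc <= 100))
  expect_true(all(sc$thermal_awareness >= 0 & sc$thermal_awareness <= 100))
  # awareness recomputes from the stored confidence and accuracy
  expect_equal(sc$thermal_awareness,
               100 - abs(sc$thermal_confidence_vas - sc$thermal_iacc))
})
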