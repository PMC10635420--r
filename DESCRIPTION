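Package: thermoception
Title: Scoring and Validation of a Thermal-Imaging Interoception Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a thermoception (thermal interoception) task in which
    radiant heat stimuli of graded intensity are delivered to the palm while a
    thermal infrared camera records hand temperature. Reads FLIR-style
    area-of-interest (AOI) temperature exports or raw frame stacks, computes
    per-trial real hand temperature change, derives standardized hand
    temperature change (SHTC) and thermal interoceptive accuracy and awareness
    indices, and scores the companion heartbeat counting task. Includes the
    validation analyses (random-intercept mixed models with Type III Wald
    tests and Bonferroni post hocs, paired t tests, Bonferroni-corrected
    Pearson correlations with default Jeffreys-Zellner-Siow Bayes factors,
    Cronbach's alpha, exploratory regressions on thermosensitivity and
    interoceptive-sensibility questionnaires), a synthetic study generator
    with a configurable psychophysical observer model, and an end-to-end
    reproduction pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    lme4,
    car,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    tiff,
    withr
Config/testthat/edition: 3
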