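---
title: "Measuring thermal interoception: models, indices and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring thermal interoception: models, indices and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoception)
```

## The measurement problem

Interoception research has leaned heavily on the heartbeat counting task
(HCT), yet accuracy in one bodily channel does not generalize to others.
The thermoception task measures a different channel: awareness of changes in
peripheral body temperature. Radiant heat stimuli at five intensity levels
(0, 25, 50, 75, 100 % of a heat source's maximum) are delivered to the palm
for 20 s, three trials per level in randomized order, while a thermal
infrared camera records the hand. After each trial the participant rates the
perceived change on a 0--100 visuo-analog scale (VAS); at the end of the
task they rate their overall confidence once.

This package implements the full computational chain for that task: AOI
temperature extraction, the accuracy/awareness indices for both the thermal
and the cardiac modality, the validation statistics, and a synthetic-data
generator so that every stage is testable without access to raw recordings.

## From thermal recordings to a trial score

A trial's recording reduces to a time series of mean AOI temperatures. When
raw frame stacks are supplied, `aoi_mean_series()` averages, per frame, the
pixels whose centers fall inside the palm polygon. The rasterisation rule is
fixed for determinism: pixels occupy unit squares in 0-based (row, col)
coordinates with the origin top-left, a pixel belongs to the AOI when its
center lies strictly inside the polygon, and centers exactly on an edge
follow the ray-casting half-open convention (top/left boundaries in,
bottom/right out). Membership is computed once and reused across frames, so
content outside the AOI can never leak into the series.

The *real hand temperature change* of a trial is the signed difference
between the last and first entries of the series (`real_change()`); nothing
between the endpoints enters the score, so the camera's frame rate and any
intermediate downsampling are irrelevant to scoring. Recordings are screened
by `qc_trial()` for out-of-range temperatures and implausible one-sample
jumps; flagged trials are reported, never silently dropped, mirroring a
workflow in which a human inspects the recording.

## The interoception indices

Within each participant, absolute changes are rescaled by the largest
absolute change across **all** of their trials (baseline trials included):

$$\mathrm{SHTC}_i = \frac{|\Delta T_i|}{\max_j |\Delta T_j|} \times 100$$

The implementation computes the ratio before multiplying by 100, which keeps
SHTC inside [0, 100] in floating point (the algebraically equivalent
`|dT|*100/max` can exceed 100 by one ulp). If every trial of a participant
has exactly zero change the standardization is undefined and the package
raises a degenerate-participant error rather than guessing.

Thermal interoceptive accuracy averages the per-trial agreement between
standardized real change and the rated change:

$$\mathrm{IAcc}_{th} = \frac{1}{N}\sum_i \left(100 - \left|\mathrm{SHTC}_i -
\mathrm{VAS}_i\right|\right)$$

The headline index uses only the active levels (25--100 %): judging "no
change" at the baseline level is an easier, qualitatively different
judgement, and per-level accuracy is empirically flat across the active
levels. The standardization itself always uses all 15 trials. With 3 trials
at each of 4 active levels, N is nominally 12; missing trials reduce N
rather than being imputed.

Cardiac accuracy uses the standard heartbeat-counting (Schandry) score,

$$\mathrm{IAcc}_{ca} = \frac{1}{N}\sum_i 100\left(1 -
\frac{|\mathrm{recorded}_i - \mathrm{perceived}_i|}{\mathrm{recorded}_i}
\right)$$

over the four counting intervals (25, 35, 45, 100 s). Severe over-counting
(perceived more than twice recorded) drives trial scores negative; they are
kept by default because discarding them hides exactly the behaviour the
score is meant to expose, and a `clip_at_zero` option exists for the
convention that floors the scale at 0.

Awareness, in both modalities, is metacognitive calibration against the
single end-of-task confidence rating:
$\mathrm{IAware} = 100 - |\mathrm{confidence} - \mathrm{IAcc}|$. It is
symmetric in its arguments and bounded in [0, 100] whenever accuracy is.

## The synthetic observer

`simulate_study()` generates complete datasets with the statistical
structure the analyses assume. Defaults are the study conditions: 31
participants, 15 thermal trials (3 per level, shuffled within participant),
baseline palm temperature Normal(32.39, 1.24) degC, mean warming of 0.05 /
0.65 / 1.49 / 2.11 / 2.35 degC across the five levels (the cumulative sums
of the reported adjacent-level warming differences), and four HCT intervals.

Trial-level choices, each made once and documented here:

* **True change.** Normal around the level mean with SD 0.35 degC between
  trials plus a participant-level susceptibility shift (SD 0.15 degC) that
  gives the mixed models a genuine random-intercept variance. Active-level
  draws are truncated at zero (radiant heating cannot cool the hand); the
  0 % level is left untruncated, allowing the small negative drift expected
  from evaporative cooling after the water bath.
* **Warming curve.** Exponential approach to baseline + delta with time
  constant one third of the 20-s stimulation, sampled at 1 Hz. Only the
  first and last samples matter downstream, so the curve shape affects
  realism only; the endpoints are kept noise-free measurement anchors and
  interior samples get 0.02 degC camera noise. The ground truth stores both
  the latent draw and the realized first-to-last difference, and the
  observer responds to the realized change, so a noise-free unit-gain
  observer scores exactly 100 end to end -- in floating point, not merely
  approximately.
* **Response model.** Perceived VAS = clip(gain x SHTC + bias + noise,
  0, 100) with participant-level gain ~ Normal(0.8, 0.25) and bias ~
  Normal(10, 10). Response noise is magnitude-dependent (Weber-like): the
  trial SD is `vas_noise_sd` (default 25) scaled by
  `0.25 + 0.75 * SHTC/100`. A constant-noise observer was considered and
  rejected because it cannot reproduce a robust empirical signature of the
  task -- trials with no felt change are judged far more consistently than
  large changes, which is what makes accuracy highest at the 0 % level.
* **Confidence.** One rating per task, clipped Normal around the
  participant's realized accuracy (bias +5, SD 12): confidence tracks
  competence imperfectly, giving awareness scores high but below ceiling.
* **Heartbeat counting.** Participant heart rate Normal(70, 10) bpm with 2
  bpm trial jitter; recorded beats = round(HR x duration / 60); perceived =
  round(attenuation x recorded + Normal(0, 2)) floored at 0, with
  attenuation ~ Normal(0.5, 0.3) clipped to [0, 1]. Attenuated counting is
  the dominant empirical finding in HCT work and yields mean accuracy near
  50 with wide individual spread.
* **Questionnaires.** Item responses are integer Likert draws around a
  participant subscale level equal to the scale midpoint plus a configured
  effect times the participant's standardized latent accuracy plus noise
  (subscale SD 0.8, item SD 0.7). All effects default to zero, so by default
  questionnaires carry no information about task performance; effects are
  switched on explicitly for parameter-recovery studies.

What the generator deliberately does **not** model: biophysical skin heat
transfer, room-temperature drift, excluded participants, motion artifacts,
or response styles beyond linear gain/bias. Passing tests on synthetic data
therefore demonstrate that the pipeline recovers what this observer model
puts in -- they do not certify the task's validity on real skin.

## Statistical toolchain

* **Intensity effects.** `fit_intensity_model()` fits
  `dv ~ intensity + (1 | participant)` by REML (lme4; an ML flag exists),
  tests the categorical intensity term with a Type III Wald chi-square
  (car), and computes all 10 pairwise level contrasts on estimated marginal
  means (emmeans) with Bonferroni adjustment over the pair count. Contrast
  degrees of freedom are asymptotic; no Kenward-Roger or Satterthwaite
  correction is applied, and contrasts are reported as lower minus higher
  level, so monotone warming yields negative estimates. Singular fits warn
  with a diagnosis instead of failing; a single participant is an error
  because the random intercept is unidentifiable.
* **Modality comparison.** Classical paired t tests on cardiac minus
  thermal scores. Differences with zero variance (including identical
  inputs) raise an error: the t statistic is 0/0 there, and silently
  reporting t = 0 would fabricate a result.
* **Correlations.** Pearson r with two-sided t-approximation p values and a
  family-wise Bonferroni cutoff of 0.05 divided by the number of pairs
  (0.0125 for the standard four-pair family). Each correlation carries a
  default Bayes factor.
* **Bayes factor.** `jzs_correlation_bf()` implements the default two-sided
  Bayes factor for a correlation with the stretched-beta prior
  ((rho+1)/2 ~ Beta(1/kappa, 1/kappa), width kappa = 1, the JASP default;
  exposed as a parameter). The marginal likelihood integrates the exact
  reduced likelihood of r over rho with `stats::integrate` at a relative
  tolerance of 1e-10; the Gauss hypergeometric factor is summed by power
  series to 1e-15. The test suite verifies agreement to 1e-6 with an
  independent oracle that uses the Euler integral representation and
  Simpson quadrature on a fixed grid, plus the sign symmetry and the
  monotone growth of null evidence with n.
* **Reliability.** `cronbach_alpha()` computes
  $\alpha = \frac{k}{k-1}\bigl(1 - \sum s_i^2 / s_{total}^2\bigr)$ with
  n-1 sample variances; it matches the two-item closed form
  $2\rho/(1+\rho)$ exactly when item variances are equal. In the pipeline,
  thermal reliability treats the four active levels as items (per-level mean
  trial accuracy per participant) and cardiac reliability treats the four
  intervals as items.
* **Exploratory regressions.** OLS of thermal accuracy on two fixed
  predictor sets -- thermosensitivity (STRAQ-1 High Temperature Sensitivity,
  Solitary and Social Thermoregulation; ETSRS Heat Perception and
  Heat-Induced Warming) and interoceptive sensibility (eight MAIA-2
  subscales plus the BPQ-SF) -- with Type III Wald chi-squares and, in the
  coefficient table, Bonferroni-adjusted p values across the predictor
  terms. The adjusted column exists because "which single subscale drives
  the effect" is inherently a family-wise question: with nine predictors at
  an unadjusted 0.05, some null slope is spuriously significant in roughly a
  third of datasets, so parameter-recovery claims are evaluated on the
  adjusted scale.
* **Design helper.** `required_n_correlation()` is the Fisher-z closed form
  $n = ((z_{1-\alpha/2} + z_{power})/\operatorname{atanh} r)^2 + 3$, rounded
  up; at r = 0.49, power 0.8, alpha 0.05 it gives 31.

## Questionnaire scoring

Subscale scores are means of constituent items on each instrument's own
response scale, after un-reversing any reverse-coded items. The
item-to-subscale key ships as an editable YAML file with the published
subscale sizes (ETSRS 5 + 7 items; STRAQ-1 7 + 8 + 5; MAIA-2 4/6/5/7/5/4/3/3;
BPQ-SF 22) and synthetic placeholder item ids; studies substitute their own
ids and reverse lists. Response ranges default to the published scales; the
ETSRS is described inconsistently in the source literature ("6-point" with
endpoints 1 and 7), so the key defaults to 1--7 and is user-overridable. The
missing-item policy is strict by default (error), with an opt-in
available-item mean guarded by a minimum-coverage threshold.

## Numerical and degenerate-input policy

Errors are classed conditions (`thermo_input_error`, `thermo_parse_error`,
`thermo_degenerate_error`, ...) so pipelines can react programmatically.
Undefined statistics -- SHTC with all-zero changes, correlations of
constants, alpha with zero total variance, t on zero-variance differences,
|r| = 1 in the Bayes factor -- raise errors rather than returning sentinel
values. Truncated normal draws use the inverse-CDF construction, which is
exact and keeps seeded runs bit-reproducible across platforms. All
randomness flows through a single seed; `run_study()` records the seed and a
configuration hash in its provenance table.

## Problem sizes in the test suite

The Monte-Carlo checks run at sizes chosen to make their binomial error
bands informative while keeping the default suite quick: 500 replicates for
the null calibration of the intensity Wald test (type I band 0.03--0.07 at
nominal 0.05), 200 replicates for its power under the default warming
profile, 200 replicates at n = 500 participants for questionnaire parameter
recovery, 1000 random participants for the formula-oracle equivalence, and
n = 10^4 for the null behaviour of Cronbach's alpha.

## Known limitations

* The observer model is linear in SHTC with clipping; real raters may show
  compressive psychophysical functions, anchoring, or sequence effects.
* The AOI stage assumes a static polygon; there is no hand tracking, motion
  correction, emissivity calibration, or native radiometric-format parsing
  (inputs are exported CSV series or plain matrix stacks).
* Mixed-model inference is asymptotic Wald; with only a handful of
  participants, contrast p values will be anticonservative.
* Negative cardiac scores and the resulting out-of-range awareness values
  are propagated, not masked; consumers comparing against clipped published
  scales should use `clip_at_zero`.
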