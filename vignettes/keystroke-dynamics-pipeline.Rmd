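---
title: "Keystroke dynamics as a longitudinal digital biomarker: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keystroke dynamics as a longitudinal digital biomarker: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keytype)
```

## The problem

Typing on a smartphone keyboard engages both fine upper-limb motor control
and cognitive processing. In chronic neurological disease — multiple
sclerosis is the motivating case — clinic visits every three months are too
sparse to track function on the individual level, while typing happens
almost daily. `keytype` implements a complete pipeline that turns raw
press/release keyboard event logs into interpretable latency composites and
quantifies, with mixed models, how those composites track two standard
clinical outcomes:

* the Nine-Hole Peg Test (NHPT), a timed upper-limb dexterity task (four
  trials averaged; higher = worse), and
* the Symbol Digit Modalities Test (SDMT), a 90-second symbol-digit
  substitution count of processing speed (higher = better; improves with
  repetition through practice).

## From events to features

The unit of raw data is a keystroke event: subject, millisecond timestamp,
press or release, and a key class (alphanumeric, backspace, punctuation,
other). Events are segmented into typing sessions wherever the gap between
consecutive events exceeds `max_gap_s` (default 5 s). The bound exists
because every feature below is a latency between neighbouring events: without
a session boundary, the pause while a phone sits in a pocket would enter the
latency distributions. 5 s preserves normal typing rhythm while excluding
off-keyboard pauses; it is configurable.

Within a session, presses and releases are paired per key token (k-th press
with k-th release; an inverted pair discards the release and keeps the press
unmatched), and eight features are derived:

| Feature | Definition | Class |
|---|---|---|
| HT | hold time: release − press of one key | alphanumeric |
| PPL | press-press latency of adjacent keys | alphanumeric |
| RRL | release-release latency of adjacent keys | alphanumeric |
| FT | flight time: next press − release | alphanumeric |
| preCS | pause before a backspace burst | backspace |
| CD | duration of a backspace burst (first press to last release) | backspace |
| postCS | pause after a backspace burst | backspace |
| APP | pause after a punctuation key | punctuation |

Design choices the definitions do not force:

* PPL/RRL/FT require the two alphanumeric key instances to be *adjacent*:
  a pair interrupted by a backspace or punctuation key emits no sample, so
  the timing features stay purely motor.
* Flight time may be negative under rollover typing (next key pressed before
  the previous is released); clamping it would bias the latency
  distributions that the clusters average, so it is retained.
* A maximal run of consecutive backspaces is one correction burst; for a
  single backspace the correction duration equals its hold time.
* Space, return and shift are classified `other`: they interrupt timing
  pairs but generate no samples. The punctuation set (default `. , ; : ! ?`)
  is configurable.
* Samples are dated by the calendar date (UTC by default, timezone
  configurable) of their first contributing event.
* An optional per-sample cap (`cap_s`) exists but is off by default; the
  session bound already limits pauses.

## Daily records and cluster scores

Per subject, day and feature, the daily value is the average of the day's
sample mean and sample median — one number per day on the seconds scale that
uses both summaries without carrying two collinear columns forward. Days
with fewer than 50 raw press+release events are removed entirely: with less
data than that, a daily latency summary is mostly noise.

Two composites are then built:

* **FMSC** (fine motor score cluster), candidates {PPL, RRL, HT, FT},
  aggregated over ±14 days around each clinical visit;
* **CSC** (cognition score cluster), candidates {preCS, CD, postCS, APP},
  aggregated over ±7 days.

The wider motor window reflects that fine motor function is the more stable
trait; the cognition composite is allowed to move faster. Windows are
inclusive of the visit day, so they admit up to 29 and 15 calendar days.

Cluster membership is not assumed: on the pooled subject-day matrix of a
candidate group, a feature enters the final cluster only if

1. it sits in the largest candidate subset whose pairwise Pearson
   correlations all exceed `r_min = 0.50` (strict inequality), and
2. it contributes comparably to the first principal component of the
   standardized candidate matrix: `|loading| >= tau * max|loading|` with the
   majority loading sign. "Comparable contribution" is not a standard
   statistic; `tau = 0.7` was chosen as tolerant of mild loading imbalance
   while rejecting a feature decoupled from the shared component, and it is
   configurable. The PCA uses the correlation matrix (column-standardized
   data): the candidates live on different scales of variability, and the
   screen should not be dominated by the widest feature.

On data with the intended structure this yields FMSC = {PPL, RRL, FT} (hold
time decouples from the latency features) and CSC = {preCS, postCS, APP}
(correction duration reflects burst mechanics rather than pausing).
Memberships can also be pinned by configuration to run a fixed composite on
any dataset.

Daily cluster values are unweighted means of the member features' daily
values, and window scores are means of the daily cluster values. The
alternative order — per-feature window means, then the cluster mean — is
implemented behind `averaging_order = "feature_first"` for sensitivity
analysis; the orders differ only when member features have unequal day
coverage, and the default weights days equally.

## The longitudinal models

For each outcome the package fits a ladder of REML linear mixed models with
a subject-level random intercept (Wald 95% CIs):

1. intercept-only (total variance `V0`),
2. outcome ~ cluster score,
3. outcome ~ cluster score + covariates (NHPT: age, sex; SDMT: age, sex,
   education coded as an unordered low/middle/high factor),
4. the **hybrid** model, which splits the cluster score `X_ij` into the
   subject mean over modeled visits (`X̄_i`, between-subject column) and the
   per-visit deviation (`X_ij − X̄_i`, within-subject column):

   `Y_ij = β0 + β_between · X̄_i + β_within · (X_ij − X̄_i) + covariates + u_i + ε_ij`

The overall slope of model 2 entangles cross-sectional differences with
longitudinal change; the hybrid decomposition separates them, which is what
makes the composite usable for monitoring an individual. Deviations sum to
zero within subject by construction, and `X̄_i` is computed from the modeled
(complete-case) visits only — grand-mean centering would change only the
intercept.

Reported alongside the coefficients:

* **explained variance**: `100 · (V0 − V_model)/V0`, the proportional
  reduction in total random-effect + residual variance against the
  intercept-only model;
* **covariate relevance** by the change-in-estimate rule: covariates are
  relevant when the cluster coefficient moves by ≥ 10% upon their inclusion;
* **SD-scaled effects**: `β × SD(X)`, the outcome change per one SD of the
  cluster score (reported to one decimal, two when the magnitude is below
  1), which makes coefficients comparable across composites.

For the SDMT, repetition produces practice gains that are common to a
measurement occasion. A per-day random intercept is not estimable with one
observation per subject-day, so the package implements the time effect as a
crossed random intercept over the scheduled occasion (M0…M12), which absorbs
occasion-common shifts; a fixed linear days-since-baseline term can be used
as a sensitivity alternative by adding `days_since_baseline` to the
covariates. NHPT scores above 40 s are set missing (an attention/recording
artifact rule) and counted in the filtering report.

## The synthetic cohort generator

No participant-level data ship with the package, so the generator is a
first-class module that produces the study conditions with known ground
truth:

* 102 subjects, visits scheduled at days 0, 91, 182, 273, 365 (M0…M12) with
  ~5-day schedule jitter; visit missingness drawn per occasion
  (0/9/25/43/12%, concentrated mid-study), optionally with monotone dropout.
* Subject-level latent latencies are log-normal across subjects — motor
  0.43 s (between-SD 0.15) and cognitive 0.94 s (between-SD 0.39) — with
  Gaussian per-visit deviations (within-SD 0.05 and 0.10 s). The
  between/within split is an assumption (no decomposition is published for
  these composites); the marginal SDs reproduce the cohort scale 0.16 and
  0.41 s.
* Education and age shift the latent cognitive latency (low/middle education
  +0.25/+0.10 s; +0.004 s per year over 46.4), making them genuine
  confounders of the SDMT association, as the covariate-relevance rule
  expects to detect.
* Event streams: alphanumeric flight gaps centred so that the extracted
  daily FMSC equals the day's latent motor value (the flight-gap target is
  `latent − 2·hold/3`, since FMSC averages PPL, RRL and FT and hold time
  enters those with weights 1, 1, 0); backspace bursts (5% of keys) and
  punctuation (6%) with pre/post pauses centred on the latent cognitive
  value; hold times ~0.09 s; occasional session breaks. Typing occurs on 90%
  of days, with a log-normal daily event count (default mean 400), and —
  by default — only on days inside some visit window (`days_mode =
  "windows"`), since other days cannot enter any downstream quantity;
  `days_mode = "full"` simulates every study day.
* Clinical scores are linear in the subject's attended-visit mean latent
  value (between coefficient) and the per-visit deviation (within
  coefficient): NHPT 15.9/6.9 s per second of motor latency; SDMT
  −11.2/−0.4 points per second of cognitive latency, plus a practice gain of
  1.5 points per occasion with a small occasion-level random shift. NHPT
  visits are drawn as four trials centred on the visit score; 3.5% of visits
  receive a +35 s contamination shift so the 40-s outlier rule has work to
  do. The shift is deliberately large enough that an artifact visit always
  exceeds the rule regardless of the subject's level: an artifact that
  evaded its own exclusion rule would act as outcome-dependent selection,
  which the linear ground truth does not describe.

Two distributional choices deserve explanation:

* **Within-day draws are truncated Gaussian, not log-normal.** The daily
  summary is (mean + median)/2. For a skewed within-day law that summary is
  biased away from the latent target whenever the per-day sample count is
  small, so the generator would fail to mean-identify its own ground truth
  at realistic event counts. A symmetric within-day law keeps the daily
  summary centred on the latent value at any event count. Skewness is kept
  where it matters scientifically — across subjects, via the log-normal
  baselines.
* **Truncation is symmetric around the target.** Gaps must stay inside
  (0, max_gap) to remain within a session. Truncating at fixed bounds would
  under-measure subjects whose latent latency approaches the bound — and
  those tail subjects carry high leverage on the between-subject slope.
  Symmetric truncation (half-width `min(3·sd, distance to either bound)`)
  keeps the draw mean exactly on target for every latent value.

Because the clinical linkage is defined on the attended-visit mean (drawn
after missingness), the hybrid decomposition estimates exactly the
generating coefficients; recovery bias therefore measures the pipeline, not
a generator artifact.

What the generator does **not** emulate: linguistically structured text,
autocorrect events, multi-device use, within-day circadian structure,
autocorrelated day-to-day drift (an AR(1)-free per-visit deviation is used),
or informative missingness (attendance is independent of the latent state).
Passing recovery tests therefore show that the pipeline estimates what it
claims under a faithful generative model of the *measurement process*; they
cannot certify behavior under violations the generator does not produce.

## Numerical and testing choices

* Timestamps are integer milliseconds; sub-millisecond input is truncated.
* Pairing of presses and releases is positional per key token; inverted
  pairs are discarded and tallied, unmatched presses are kept (they still
  support press-based latencies).
* The correlation screen uses strict `r > r_min`, so a pair at exactly 0.50
  does not cohere; subset ties are broken by the higher mean pairwise
  correlation.
* Singular mixed-model fits (a variance component at zero) are flagged, not
  errors; non-convergence is an error carrying the optimizer message.
* Explained variance may be negative (the covariate model can add total
  variance in small samples); it is reported with a warning rather than
  floored.
* Rounding happens only in the reporting layer (`sd_scaled_effect`,
  `rate_pct`); all stored values keep full precision.
* The test suite validates the extractors against a brute-force loop-based
  oracle on random malformed-ish streams, checks the algebraic identities of
  the hybrid design exactly, and runs a 200-replicate end-to-end recovery
  study (102 subjects, reduced event counts of ~60/day for runtime) asserting
  |mean bias| ≤ 2 Monte-Carlo SEs and ≥ 90% Wald CI coverage per
  coefficient. Problem sizes in the routine tests (small cohorts, reduced
  event counts) are chosen to keep the suite fast; the generator's defaults
  remain the study-scale conditions.

## Known limitations

* Wald CIs and z-tests, not profile or Satterthwaite: adequate at ~100
  subjects, anti-conservative in small samples.
* The hybrid between column uses the observed visit mean; with few visits
  per subject this is a noisy stand-in for the subject's long-run mean
  (classical errors-in-variables on the between axis). At five visits and
  the default variance split the induced attenuation is well under the
  Monte-Carlo noise of the recovery study.
* The occasion random intercept absorbs occasion-common practice effects
  but not subject-specific practice slopes.
* Day-level aggregation assumes the within-day sample mean/median is a
  sufficient daily summary; time-of-day and fatigue structure are discarded.
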