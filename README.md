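# keytype

Keystroke dynamics — the timing of presses and releases during everyday
smartphone typing — carries information about fine motor control and
cognitive processing. `keytype` is an R package for turning raw keyboard
event logs into longitudinal digital-biomarker analyses: it derives the
standard keystroke timing features, builds two composite latency scores (a
fine motor cluster and a cognition cluster), and quantifies their
association with clinical outcomes — the Nine-Hole Peg Test (NHPT, upper
limb) and the Symbol Digit Modalities Test (SDMT, processing speed) — using
random-intercept and hybrid between-/within-subject linear mixed models. It
is aimed at researchers analyzing passive-monitoring keyboard data in
multiple sclerosis and similar longitudinal settings.

## The model in brief

From press/release events, eight features are extracted per typing session:
hold time (HT), press-press latency (PPL), release-release latency (RRL),
flight time (FT) for alphanumeric keys; pre-correction slowing (preCS),
correction duration (CD) and post-correction slowing (postCS) around
backspace bursts; and the after-punctuation pause (APP). Daily values are
the average of the day's sample mean and median; days with fewer than 50
events are dropped. Candidate features are screened by pairwise correlation
(r > 0.50) and first-principal-component contribution, yielding the fine
motor score cluster FMSC = {PPL, RRL, FT} (±14-day visit windows) and the
cognition score cluster CSC = {preCS, postCS, APP} (±7-day windows).

Window scores X_ij enter mixed models with subject random intercepts u_i:

    Y_ij = b0 + b1 X_ij + covariates + u_i + e_ij            (overall)
    Y_ij = b0 + b_between X̄_i + b_within (X_ij − X̄_i)
           + covariates + u_i + e_ij                          (hybrid)

where X̄_i is the subject's mean score over modeled visits. `b_between`
captures differences across subjects, `b_within` change within a subject —
the quantity that matters for individual monitoring. SDMT models add a
crossed random intercept over measurement occasion to absorb practice
effects. Reporting includes explained variance (proportional reduction in
total variance vs the intercept-only model), the 10% change-in-estimate
covariate rule, and SD-scaled effect sizes.

Because the underlying study data are not deposited, the package ships a
synthetic cohort generator (`simulate_cohort()`) that emulates the study
conditions — 102 subjects, five visits over a year, cluster scales 0.43 s
(SD 0.16) and 0.94 s (SD 0.41), visit missingness concentrated mid-study,
an SDMT practice effect — with known ground-truth coefficients, so the
entire pipeline is testable end to end.

## Worked example

A small event log ships with the package (3 subjects, 6 days with known
event counts):

```r
library(keytype)

ev <- read_events(system.file("extdata", "toy_events.csv", package = "keytype"))
sessions <- segment_sessions(ev, max_gap_s = 5)
samples  <- extract_features(sessions)
head(samples, 3)
#>    subject_id       date feature value_s
#> 1:        T01 2019-03-01     PPL   0.361
#> 2:        T01 2019-03-01     PPL   0.494
#> 3:        T01 2019-03-01     PPL   0.367

daily <- aggregate_daily(samples, ev, min_events = 50)
daily[daily$feature == "PPL",
      c("subject_id", "date", "n_samples", "daily_value", "day_event_count")]
#>    subject_id       date n_samples daily_value day_event_count
#> 1:        T01 2019-03-02        16   0.4809062              50
#> 2:        T01 2019-03-03        38   0.5002500             120
#> 3:        T02 2019-03-01       123   0.4727033             300
#> 4:        T03 2019-03-05        20   0.4950250              50
```

Each sample is one latency in seconds (the first rows are press-press
latencies around 0.36–0.49 s, ordinary typing speed). Two of the six days
are gone from the daily table: T01's first day logged 49 events and T02's
second only 12, so both fall under the 50-event threshold; the retained
daily values are `(mean + median)/2` of that day's samples.

A full analysis on a simulated cohort:

```r
co  <- simulate_cohort(cohort_config(events_per_day = list(mean = 100, sd = 25)),
                       seed = 3)
rpt <- run_pipeline(co$events, co$visits, pipeline_config(), seed = 3)
rpt$cluster_definitions$FMSC
#> <cluster FMSC> members: {PPL, RRL, FT} of {PPL, RRL, HT, FT}; window: +/-14 days
subset(as.data.frame(rpt$model_table), outcome == "nhpt" & model == "hybrid")
#>  outcome  model    term     beta     ci_lo    ci_hi            p total_variance explained_pct
#>     nhpt hybrid between 14.75030 12.598006 16.90260 3.916455e-41       6.374721      54.45217
#>     nhpt hybrid  within 10.60432  6.351115 14.85753 1.025468e-06       6.374721      54.45217
```

The hybrid rows read: a 1-second increase in the fine-motor cluster score
corresponds to a ~14.8 s worse NHPT across subjects and ~10.6 s within a
subject over time on this particular simulated cohort (generating values
15.9 and 6.9; a single replicate carries Monte-Carlo error). `write_report()`
serializes the full model ladder, descriptives and filtering log as JSON +
CSV.

## Package layout

- `R/events_io.R` — event reading/validation, key classification, sessions
- `R/features.R` — the eight keystroke features
- `R/aggregation.R` — daily records, daily cluster values, visit windows
- `R/cluster_construction.R` — correlation + PCA screens, cluster definitions
- `R/models.R` — visit table preparation, mixed models, hybrid decomposition,
  explained variance, covariate relevance, SD scaling
- `R/simulate.R` — the synthetic cohort generator
- `R/pipeline.R` — orchestration, reporting
- `vignettes/keystroke-dynamics-pipeline.Rmd` — the methods vignette: model
  assumptions, parameter choices, generator design, limitations
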