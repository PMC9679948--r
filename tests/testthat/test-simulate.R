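small_cfg <- function(...) {
  cohort_config(n_subjects = 8, events_per_day = list(mean = 80, sd = 10),
                ...)
}

test_that("identical seeds reproduce the cohort byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(small_cfg(), seed = 42, out_dir = d1)
  simulate_cohort(small_cfg(), seed = 42, out_dir = d2)
  for (f in c("events.csv", "visits.csv", "ground_truth.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  d3 <- withr::local_tempdir()
  simulate_cohort(small_cfg(), seed = 43, out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "events.csv")),
                         readLines(file.path(d3, "events.csv"))))
})

test_that("cohort dimensions respect the configuration", {
  co <- simulate_cohort(small_cfg(), seed = 7, events = FALSE)
  expect_equal(nrow(co$subjects), 8L)
  expect_lte(nrow(co$visits), 8L * 5L)
  expect_equal(nrow(co$ground_truth), 8L * 5L)
  expect_setequal(unique(co$ground_truth$visit_label),
                  c("M0", "M3", "M6", "M9", "M12"))
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(adherence = 1.2), "probabilities")
  expect_error(cohort_config(visit_days = c(0, 91, 91, 273, 365)),
               "strictly increasing")
})

test_that("simulated event streams satisfy the session invariants", {
  ev <- simulate_day_events(0.43, 0.94, n_events = 400, seed = 9)
  expect_equal(nrow(ev), 400L)
  expect_true(all(diff(ev$timestamp_ms) >= 0))
  # every release follows its matching press
  evd <- as.data.frame(ev)
  for (tok in unique(evd$key_token)) {
    sub <- evd[evd$key_token == tok, ]
    expect_equal(sub$action, c("press", "release"))
    expect_gte(diff(sub$timestamp_ms), 0)
  }
})

test_that("the extracted daily latencies match the latent targets", {
  cfg <- cohort_config()
  ev <- simulate_day_events(0.43, 0.94, n_events = 2000, config = cfg,
                            seed = 10)
  d <- aggregate_daily(extract_features(segment_sessions(ev)), ev)
  # the latent value parameterizes the cluster composite: the fine motor
  # cluster centres on it, PPL on latent + hold/3
  fmsc <- mean(d$daily_value[d$feature %in% c("PPL", "RRL", "FT")])
  expect_equal(fmsc, 0.43, tolerance = 0.02 / 0.43) # within +/- 0.02 s
  ppl <- d$daily_value[d$feature == "PPL"]
  expect_equal(ppl, 0.43 + cfg$typing$hold_mean / 3,
               tolerance = 0.02 / 0.43)
  csc <- mean(d$daily_value[d$feature %in% c("preCS", "postCS", "APP")])
  expect_equal(csc, 0.94, tolerance = 0.05 / 0.94)
})

test_that("a zero punctuation rate produces no after-punctuation pauses", {
  cfg <- cohort_config()
  cfg$typing$p_punct <- 0
  ev <- simulate_day_events(0.43, 0.94, 600, config = cfg, seed = 11)
  f <- extract_features(segment_sessions(ev))
  expect_equal(nrow(f[f$feature == "APP", ]), 0L)
  expect_gt(nrow(f[f$feature == "preCS", ]), 0L)
})

test_that("rollover flag produces negative flight times", {
  cfg <- cohort_config()
  cfg$typing$p_rollover <- 0.2
  ev <- simulate_day_events(0.43, 0.94, 1000, config = cfg, seed = 12)
  f <- extract_features(segment_sessions(ev))
  expect_gt(sum(f$value_s < 0 & f$feature == "FT"), 0L)
})

test_that("missingness rates are honoured", {
  sched <- expand.grid(subject_id = sprintf("s%03d", 1:200),
                       visit_label = c("M0", "M3", "M6"),
                       stringsAsFactors = FALSE)
  # all-zero rates: identity
  r0 <- c(M0 = 0, M3 = 0, M6 = 0)
  expect_equal(nrow(apply_missingness(sched, r0, seed = 1)), nrow(sched))
  # rate 1 removes the occasion entirely
  r1 <- c(M0 = 0, M3 = 0, M6 = 1)
  out1 <- apply_missingness(sched, r1, seed = 1)
  expect_equal(sum(out1$visit_label == "M6"), 0L)
  expect_equal(sum(out1$visit_label == "M0"), 200L)
  # study-like rates: retained counts within binomial 95% bounds
  r <- c(M0 = 0, M3 = 0.09, M6 = 0.25)
  out <- apply_missingness(sched, r, seed = 2)
  for (lab in names(r)) {
    n_kept <- sum(out$visit_label == lab)
    bounds <- qbinom(c(0.025, 0.975), 200, 1 - r[[lab]])
    expect_gte(n_kept, bounds[1])
    expect_lte(n_kept, bounds[2])
  }
  expect_error(apply_missingness(sched, c(M0 = -0.1, M3 = 0, M6 = 0)),
               "\\[0, 1\\]")
})

test_that("the practice effect raises cohort SDMT across visits", {
  co <- simulate_cohort(cohort_config(), seed = 13, events = FALSE)
  v <- as.data.frame(co$visits)
  m <- tapply(v$sdmt_score, v$visit_label, mean)
  expect_gt(m[["M12"]], m[["M0"]] + 2) # rises by ~6 under defaults
})

test_that("zero noise makes clinical scores exact linear functions", {
  cfg <- cohort_config()
  cfg$nhpt$subject_sd <- 0; cfg$nhpt$resid_sd <- 0; cfg$nhpt$trial_sd <- 0
  cfg$nhpt$contam_rate <- 0; cfg$nhpt$age_effect <- 0; cfg$nhpt$sex_effect <- 0
  co <- simulate_cohort(cfg, seed = 14, events = FALSE)
  gt <- merge(as.data.frame(co$ground_truth), as.data.frame(co$visits),
              by = c("subject_id", "visit_label"))
  pred <- cfg$nhpt$intercept + cfg$nhpt$beta_between * gt$motor_bar +
    cfg$nhpt$beta_within * (gt$motor_ij - gt$motor_bar)
  nhpt <- rowMeans(gt[, paste0("nhpt_t", 1:4)])
  expect_equal(nhpt, pred, tolerance = 0.05 / mean(pred)) # trial rounding only
})

test_that("window day counts show mid-study plateau and edge truncation", {
  co <- simulate_cohort(cohort_config(), seed = 15, events = FALSE)
  defs <- build_cluster_definitions(
    co$daily, pinned = list(FMSC = c("PPL", "RRL", "FT"),
                            CSC = c("preCS", "postCS", "APP")))
  sc <- cluster_window_scores(co$daily, co$visits, defs[c("FMSC", "CSC")])
  fm <- as.data.frame(sc[sc$cluster == "FMSC", ])
  mid <- tapply(fm$n_days, fm$visit_label, mean)[c("M3", "M6", "M9")]
  expect_true(all(mid > 23 & mid < 29)) # ~26 under 90% adherence
  edge <- tapply(fm$n_days, fm$visit_label, mean)[c("M0", "M12")]
  expect_true(all(edge < 18)) # truncated at the study boundaries
})

test_that("cohort-level cluster scale matches the configured targets", {
  co <- simulate_cohort(cohort_config(), seed = 16, events = FALSE)
  defs <- build_cluster_definitions(
    co$daily, pinned = list(FMSC = c("PPL", "RRL", "FT"),
                            CSC = c("preCS", "postCS", "APP")))
  sc <- cluster_window_scores(co$daily, co$visits, defs[c("FMSC", "CSC")])
  fm <- sc$value[sc$cluster == "FMSC"]
  cs <- sc$value[sc$cluster == "CSC"]
  expect_equal(mean(fm), 0.43, tolerance = 0.05)
  expect_equal(sd(fm), 0.16, tolerance = 0.25)
  expect_equal(mean(cs), 0.94, tolerance = 0.05)
  expect_equal(sd(cs), 0.41, tolerance = 0.25)
})
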