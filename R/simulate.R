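# Synthetic longitudinal cohort generator with known ground truth.
#
# Generative structure:
#   * Per subject, latent fine-motor and cognitive typing latencies are drawn
#     log-normal across subjects (positive support, right skew), with
#     Gaussian per-visit deviations around the subject baseline.
#   * Typing-event streams are generated day by day within the visit
#     aggregation windows: alphanumeric flight gaps around the day's latent
#     motor latency, backspace bursts and punctuation pauses around the
#     latent cognitive latency. Event-level gap and hold draws are truncated
#     Gaussian so the pipeline's (mean+median)/2 daily summary is centred on
#     the latent value at any per-day event count.
#   * Clinical scores are linear in the subject's attended-visit mean of the
#     latent values (between-subject coefficient) and the per-visit deviation
#     from that mean (within-subject coefficient), plus covariate effects, an
#     SDMT practice increment per occasion and Gaussian noise. Visit
#     missingness is drawn per occasion before scores are generated.

#' Configuration of the synthetic cohort
#'
#' Defaults emulate a one-year smartphone-typing study in multiple sclerosis:
#' 102 subjects, visits every ~91 days (M0..M12, with schedule jitter),
#' fine-motor cluster latencies around 0.43 s (SD 0.16) and cognition cluster
#' latencies around 0.94 s (SD 0.41), NHPT linked to the motor latencies with
#' between/within coefficients 15.9 / 6.9 s per second of latency, SDMT
#' linked to the cognitive latencies with -11.2 / -0.4 points per second, an
#' SDMT practice increment of 1.5 points per occasion, and visit missingness
#' concentrated at M6/M9.
#'
#' @param n_subjects Number of subjects (default 102).
#' @param visit_days Scheduled visit days since baseline (strictly
#'   increasing; default `c(0, 91, 182, 273, 365)`).
#' @param visit_labels Visit labels (default `M0, M3, M6, M9, M12`).
#' @param visit_jitter_sd SD in days of the schedule jitter of follow-up
#'   visits (baseline is never jittered; default 5).
#' @param adherence Probability that a subject types on a given day
#'   (default 0.9).
#' @param events_per_day Mean and SD of the log-normal daily raw event count
#'   (default mean 400, SD 250; days below the pipeline's 50-event threshold
#'   are dropped downstream).
#' @param fmsc,csc Latent cluster targets: `mean`, `between_sd` (subject
#'   baseline SD), `within_sd` (per-visit deviation SD). Defaults solve
#'   `sqrt(between_sd^2 + within_sd^2)` to approximately the cohort SDs 0.16
#'   and 0.41.
#' @param typing Event-stream mechanics: hold-time mean/SD, gap coefficients
#'   of variation, backspace/punctuation rates, intra-burst gap range,
#'   session-break probability, rollover probability (negative flight times).
#' @param nhpt,sdmt Clinical linkage: intercept, `beta_between`,
#'   `beta_within`, subject and residual SDs, covariate effects, and for NHPT
#'   the per-trial jitter SD, contamination (slow-outlier) rate/shift and
#'   floor; for SDMT the practice increment per occasion and the occasion SD.
#' @param demographics Age mean/SD/range, probability female, education
#'   probabilities (low/middle/high).
#' @param confounding Education and age shifts of the latent cognitive
#'   latency (makes education/age genuine confounders of the SDMT link).
#' @param missingness Per-visit probability that the clinical visit is
#'   missed (named by visit label).
#' @param dropout_hazard Per-visit hazard of monotone dropout (default 0).
#' @param days_mode `"windows"` simulates typing only on days within a visit
#'   aggregation window (every other day is irrelevant downstream);
#'   `"full"` simulates every study day.
#' @param study_start Calendar date of day 0.
#' @return A validated `cohort_config` object.
#' @export
cohort_config <- function(
    n_subjects = 102,
    visit_days = c(0, 91, 182, 273, 365),
    visit_labels = c("M0", "M3", "M6", "M9", "M12"),
    visit_jitter_sd = 5,
    adherence = 0.9,
    events_per_day = list(mean = 400, sd = 250),
    fmsc = list(mean = 0.43, between_sd = 0.15, within_sd = 0.05),
    csc = list(mean = 0.94, between_sd = 0.39, within_sd = 0.10),
    typing = list(hold_mean = 0.09, hold_sd = 0.018,
                  gap_cv = 0.30, cog_cv = 0.30,
                  p_backspace = 0.05, p_punct = 0.06,
                  intra_burst_gap = c(0.03, 0.09),
                  p_session_break = 0.01, p_rollover = 0),
    nhpt = list(intercept = 14.2, beta_between = 15.9, beta_within = 6.9,
                subject_sd = 2.0, resid_sd = 1.8, trial_sd = 1.0,
                age_effect = 0.03, sex_effect = 0.3,
                contam_rate = 0.035, contam_shift = 35, floor = 5),
    sdmt = list(intercept = 66.5, beta_between = -11.2, beta_within = -0.4,
                subject_sd = 8.5, resid_sd = 4.0,
                practice_per_occasion = 1.5, occasion_sd = 0.5,
                age_effect = -0.15, sex_effect = 0,
                edu_effects = c(low = -8, middle = -4, high = 0)),
    demographics = list(age_mean = 46.4, age_sd = 10.4,
                        age_range = c(18, 65), p_female = 0.735,
                        edu_probs = c(low = 0.029, middle = 0.333,
                                      high = 0.638)),
    confounding = list(edu_cog_shift = c(low = 0.25, middle = 0.10,
                                         high = 0),
                       age_cog_slope = 0.004),
    missingness = c(M0 = 0, M3 = 0.09, M6 = 0.25, M9 = 0.43, M12 = 0.12),
    dropout_hazard = 0,
    days_mode = c("windows", "full"),
    study_start = as.Date("2019-01-01")) {
  days_mode <- match.arg(days_mode)
  cfg <- list(
    n_subjects = n_subjects, visit_days = visit_days,
    visit_labels = visit_labels, visit_jitter_sd = visit_jitter_sd,
    adherence = adherence, events_per_day = events_per_day,
    fmsc = fmsc, csc = csc, typing = typing, nhpt = nhpt, sdmt = sdmt,
    demographics = demographics, confounding = confounding,
    missingness = missingness, dropout_hazard = dropout_hazard,
    days_mode = days_mode, study_start = as.Date(study_start)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param config A `cohort_config` to validate.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with(config, {
    if (!is.numeric(n_subjects) || n_subjects < 2) {
      stop("n_subjects must be >= 2", call. = FALSE)
    }
    if (length(visit_days) != length(visit_labels) ||
        any(diff(visit_days) <= 0)) {
      stop("visit schedule must be strictly increasing and match labels",
           call. = FALSE)
    }
    probs <- c(adherence, missingness, dropout_hazard,
               typing$p_backspace, typing$p_punct, typing$p_session_break,
               typing$p_rollover, demographics$p_female,
               demographics$edu_probs)
    if (any(probs < 0 | probs > 1)) {
      stop("all probabilities must lie in [0, 1]", call. = FALSE)
    }
    sds <- c(fmsc$between_sd, fmsc$within_sd, csc$between_sd, csc$within_sd,
             typing$hold_sd, nhpt$subject_sd, nhpt$resid_sd, nhpt$trial_sd,
             sdmt$subject_sd, sdmt$resid_sd, sdmt$occasion_sd,
             visit_jitter_sd, events_per_day$sd)
    if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
    if (fmsc$mean <= 0 || csc$mean <= 0 || typing$hold_mean <= 0) {
      stop("latent latency means must be positive", call. = FALSE)
    }
    if (!all(names(missingness) == visit_labels)) {
      stop("missingness must be named by visit label", call. = FALSE)
    }
  })
  invisible(config)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<cohort_config> %d subjects, %d visits (%s)\n",
    "  FMSC %.2f s (between SD %.2f, within SD %.2f); ",
    "CSC %.2f s (between SD %.2f, within SD %.2f)\n",
    "  NHPT betas %.1f/%.1f; SDMT betas %.1f/%.1f; adherence %.2f; ",
    "days_mode=%s\n"),
    x$n_subjects, length(x$visit_days),
    paste(x$visit_labels, collapse = ","),
    x$fmsc$mean, x$fmsc$between_sd, x$fmsc$within_sd,
    x$csc$mean, x$csc$between_sd, x$csc$within_sd,
    x$nhpt$beta_between, x$nhpt$beta_within,
    x$sdmt$beta_between, x$sdmt$beta_within,
    x$adherence, x$days_mode))
  invisible(x)
}

# truncated normal via inverse-cdf (vectorized over mean/sd)
.rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# gap draws truncated SYMMETRICALLY around the target within the feasible
# range [hard_lo, hard_hi]: symmetric truncation keeps the draw mean exactly
# on target for every latent value, so daily summaries stay calibrated even
# for subjects whose latencies approach the session gap bound
.rgap <- function(n, mean, sd, hard_lo = 0.02, hard_hi = 4.6) {
  w <- pmin(3 * sd, hard_hi - mean, mean - hard_lo)
  w <- pmax(w, 1e-3)
  .rtnorm(n, mean, sd, lower = mean - w, upper = mean + w)
}

# log-normal with given arithmetic mean and sd
.rlnorm_ms <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate one day of keystroke events
#'
#' Generates a sequential press/release stream for one subject-day:
#' alphanumeric flight gaps centred so the extracted daily fine-motor cluster
#' value equals `latent_motor`; pauses before/after backspace bursts and
#' after punctuation centred on `latent_cog`. All typing-session invariants
#' hold (timestamps nondecreasing, every release after its press).
#'
#' @param latent_motor Latent fine-motor latency of the day in seconds.
#' @param latent_cog Latent cognitive latency of the day in seconds.
#' @param n_events Total press+release events (>= 2; one key instance per two
#'   events, odd counts are rounded down).
#' @param config A [cohort_config()] (only the `typing` block is used).
#' @param subject_id Subject identifier for the rows.
#' @param date Calendar date of the day.
#' @param seed Optional seed for standalone use.
#' @return Event `data.table` in the canonical schema.
#' @export
simulate_day_events <- function(latent_motor, latent_cog, n_events,
                                config = cohort_config(),
                                subject_id = "S001",
                                date = as.Date("2019-01-01"), seed = NULL) {
  stopifnot(n_events >= 2, latent_motor > 0, latent_cog > 0)
  if (!is.null(seed)) set.seed(seed)
  days <- data.table(
    day_id = 1L, subject_id = subject_id, date = as.Date(date),
    n_keys = floor(n_events / 2), motor = latent_motor, cog = latent_cog,
    start_s = as.numeric(as.POSIXct(paste(date, "09:00:00"), tz = "UTC"))
  )
  .simulate_keys(days, config$typing)
}

# vectorized event-stream builder over a table of subject-days
# days: day_id, subject_id, date, n_keys, motor, cog, start_s
.simulate_keys <- function(days, ty) {
  days <- days[n_keys >= 1L]
  if (nrow(days) == 0L) {
    return(data.table(subject_id = character(), timestamp_ms = numeric(),
                      action = character(), key_class = character(),
                      key_token = character()))
  }
  n <- days$n_keys
  kd <- days[rep(seq_len(.N), n)]
  kd[, key_i := seq_len(.N), by = day_id]
  N <- nrow(kd)

  u <- runif(N)
  kd[, key_class := fifelse(u < ty$p_backspace, "backspace",
                            fifelse(u < ty$p_backspace + ty$p_punct,
                                    "punctuation", "alphanumeric"))]
  kd[, ht := .rtnorm(.N, ty$hold_mean, ty$hold_sd, lower = 0.02)]
  kd[, prev_class := shift(key_class), by = day_id]

  # flight gap preceding each key (press - previous release)
  motor_target <- pmax(kd$motor - 2 * ty$hold_mean / 3, 0.05)
  f <- .rgap(N, motor_target, ty$gap_cv * motor_target)
  cog_idx <- which(
    (kd$key_class == "backspace" & kd$prev_class != "backspace") |
      (kd$prev_class %in% c("backspace", "punctuation") &
         kd$key_class != "backspace")
  )
  if (length(cog_idx) > 0L) {
    tgt <- kd$cog[cog_idx]
    f[cog_idx] <- .rgap(length(cog_idx), tgt, ty$cog_cv * tgt)
  }
  burst_idx <- which(kd$key_class == "backspace" &
                       kd$prev_class == "backspace")
  if (length(burst_idx) > 0L) {
    f[burst_idx] <- runif(length(burst_idx), ty$intra_burst_gap[1],
                          ty$intra_burst_gap[2])
  }
  if (ty$p_rollover > 0) {
    roll <- which(kd$key_class == "alphanumeric" &
                    kd$prev_class == "alphanumeric" &
                    runif(N) < ty$p_rollover)
    f[roll] <- -runif(length(roll), 0, 0.015)
  }
  if (ty$p_session_break > 0) {
    brk <- which(runif(N) < ty$p_session_break & kd$key_i > 1L)
    f[brk] <- f[brk] + runif(length(brk), 60, 300)
  }
  f[kd$key_i == 1L] <- 0
  kd[, f := f]

  # press_k = start + sum_{j<=k} (hold_{j-1} + f_j)
  kd[, press_s := start_s + cumsum(shift(ht, fill = 0) + f), by = day_id]
  kd[, release_s := press_s + ht]
  kd[, key_token := paste0("k", key_i)]

  ev <- rbind(
    kd[, .(subject_id, timestamp_ms = round(press_s * 1000),
           action = "press", key_class, key_token)],
    kd[, .(subject_id, timestamp_ms = round(release_s * 1000),
           action = "release", key_class, key_token)]
  )
  setorder(ev, subject_id, timestamp_ms, action)
  ev[]
}

#' Apply per-visit missingness to a visit table
#'
#' Visits are dropped independently with the configured per-occasion rates;
#' optionally a monotone dropout process removes all visits after a
#' geometric dropout time.
#'
#' @param visits Data frame with `subject_id` and `visit_label`.
#' @param rates Per-visit missingness probabilities, named by visit label
#'   (baseline is typically 0).
#' @param dropout_hazard Per-transition probability of permanent dropout
#'   (default 0).
#' @param seed Optional seed for standalone use.
#' @return The visit table restricted to retained rows.
#' @export
apply_missingness <- function(visits, rates, dropout_hazard = 0,
                              seed = NULL) {
  if (any(rates < 0 | rates > 1) || dropout_hazard < 0 ||
      dropout_hazard > 1) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  v <- as.data.table(visits)
  r <- rates[as.character(v$visit_label)]
  if (any(is.na(r))) stop("rates must be named by visit label", call. = FALSE)
  keep <- runif(nrow(v)) >= r
  if (dropout_hazard > 0) {
    v[, occ_idx := as.integer(factor(visit_label,
                                     levels = unique(visit_label)))]
    n_occ <- max(v$occ_idx)
    subj <- unique(v$subject_id)
    drop_after <- setNames(1L + rgeom(length(subj), dropout_hazard), subj)
    keep <- keep & v$occ_idx <= drop_after[as.character(v$subject_id)]
    v[, occ_idx := NULL]
  }
  v[keep][]
}

#' Simulate clinical scores from latent states
#'
#' NHPT and SDMT per attended visit, linear in the subject's attended-visit
#' mean latent value (between-subject coefficient) and the per-visit
#' deviation (within-subject coefficient), plus covariate effects, an SDMT
#' practice increment per occasion with an occasion-level random shift, and
#' Gaussian residuals. NHPT is floored at a positive value and a small
#' contamination rate produces slow outliers above the pipeline's 40-s rule.
#'
#' @param truth Visit-level truth table (from [simulate_cohort()]'s internals)
#'   with `subject_id`, `visit_label`, `occ_idx`, `motor_ij`, `cog_ij`,
#'   `motor_bar`, `cog_bar`, `age`, `sex`, `education`, restricted to
#'   attended visits.
#' @param config A [cohort_config()].
#' @param seed Optional seed for standalone use.
#' @return `truth` with `nhpt_true`, `nhpt_t1`..`nhpt_t4` and `sdmt_score`.
#' @export
simulate_clinical_scores <- function(truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- as.data.table(truth)
  nh <- config$nhpt
  sd_ <- config$sdmt
  dem <- config$demographics
  subj_re_n <- tr[, .(re = rnorm(1, 0, nh$subject_sd)), by = subject_id]
  subj_re_s <- tr[, .(re = rnorm(1, 0, sd_$subject_sd)), by = subject_id]
  occ_re <- tr[, .(re = rnorm(1, 0, sd_$occasion_sd)), by = visit_label]
  tr <- merge(tr, setnames(subj_re_n, "re", ".re_n"), by = "subject_id")
  tr <- merge(tr, setnames(subj_re_s, "re", ".re_s"), by = "subject_id")
  tr <- merge(tr, setnames(occ_re, "re", ".re_o"), by = "visit_label")

  age_c <- tr$age - dem$age_mean
  sex_m <- as.numeric(tr$sex == "male")
  nhpt_true <- nh$intercept + nh$beta_between * tr$motor_bar +
    nh$beta_within * (tr$motor_ij - tr$motor_bar) +
    nh$age_effect * age_c + nh$sex_effect * sex_m +
    tr$.re_n + rnorm(nrow(tr), 0, nh$resid_sd)
  contam <- runif(nrow(tr)) < nh$contam_rate
  nhpt_true <- pmax(nhpt_true + contam * nh$contam_shift, nh$floor)
  tr[, nhpt_true := nhpt_true]
  # four trials centred on the visit score so their mean is the true score
  trial_noise <- matrix(rnorm(4 * nrow(tr), 0, nh$trial_sd), ncol = 4)
  trial_noise <- trial_noise - rowMeans(trial_noise)
  for (i in 1:4) {
    tr[, (paste0("nhpt_t", i)) := round(pmax(nhpt_true + trial_noise[, i],
                                             0.5), 1)]
  }
  edu_eff <- sd_$edu_effects[as.character(tr$education)]
  sdmt <- sd_$intercept + sd_$beta_between * tr$cog_bar +
    sd_$beta_within * (tr$cog_ij - tr$cog_bar) +
    sd_$age_effect * age_c + sd_$sex_effect * sex_m + edu_eff +
    sd_$practice_per_occasion * (tr$occ_idx - 1L) + tr$.re_o +
    tr$.re_s + rnorm(nrow(tr), 0, sd_$resid_sd)
  tr[, sdmt_score := pmax(round(sdmt), 0)]
  tr[, c(".re_n", ".re_s", ".re_o") := NULL]
  tr[]
}

#' Simulate a full synthetic cohort
#'
#' Draws subjects (demographics, latent motor/cognitive baselines with
#' education/age confounding of the cognitive latency), a jittered visit
#' schedule, per-visit latent deviations, visit attendance, clinical scores,
#' and (optionally) the raw keystroke event streams on typing days. Fully
#' reproducible given `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed driving all randomness.
#' @param events Generate raw event streams (default `TRUE`). With
#'   `events = FALSE` a fast path emits daily feature records directly from
#'   the latent states (latent value plus day-level noise), which feeds the
#'   same downstream pipeline without event-level simulation.
#' @param out_dir Optional directory: writes `events.csv` (when simulated),
#'   `visits.csv` and `ground_truth.csv`.
#' @return List with `subjects`, `visits` (attended visits with NHPT trials,
#'   SDMT, covariates), `events` (canonical schema, or `NULL`), `daily`
#'   (fast-path daily records, or `NULL`), `ground_truth` (all scheduled
#'   visits with latent values, attendance and the generating coefficients as
#'   attribute `coefficients`), `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L,
                            events = TRUE, out_dir = NULL) {
  validate_cohort_config(config)
  set.seed(as.integer(seed))
  dem <- config$demographics
  n <- config$n_subjects
  n_vis <- length(config$visit_days)

  subjects <- data.table(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = round(.rtnorm(n, dem$age_mean, dem$age_sd,
                        lower = dem$age_range[1], upper = dem$age_range[2])),
    sex = ifelse(runif(n) < dem$p_female, "female", "male"),
    education = sample(names(dem$edu_probs), n, replace = TRUE,
                       prob = dem$edu_probs)
  )
  # latent baselines; education/age shift the cognitive latency (confounding)
  edu_shift <- config$confounding$edu_cog_shift[subjects$education]
  exp_shift <- sum(config$confounding$edu_cog_shift * dem$edu_probs)
  subjects[, motor := pmax(.rlnorm_ms(n, config$fmsc$mean,
                                      config$fmsc$between_sd), 0.10)]
  cog_base <- .rlnorm_ms(n, config$csc$mean - exp_shift,
                         config$csc$between_sd)
  subjects[, cog := pmax(cog_base + edu_shift +
                           config$confounding$age_cog_slope *
                           (age - dem$age_mean), 0.15)]

  # schedule with jitter; baseline fixed at day 0
  sched <- data.table(
    subject_id = rep(subjects$subject_id, each = n_vis),
    visit_label = rep(config$visit_labels, n),
    occ_idx = rep(seq_len(n_vis), n),
    visit_day = rep(config$visit_days, n)
  )
  jit <- round(rnorm(nrow(sched), 0, config$visit_jitter_sd))
  jit[sched$occ_idx == 1L] <- 0
  sched[, visit_day := pmin(pmax(visit_day + jit, 0), max(visit_day) + 21)]
  sched[, visit_date := config$study_start + visit_day]

  truth <- merge(sched, subjects, by = "subject_id")
  truth[, motor_ij := pmax(motor + rnorm(.N, 0, config$fmsc$within_sd), 0.08)]
  truth[, cog_ij := pmax(cog + rnorm(.N, 0, config$csc$within_sd), 0.10)]

  attended_rows <- apply_missingness(truth, config$missingness,
                                     config$dropout_hazard)
  truth[, attended := paste(subject_id, visit_label) %in%
          attended_rows[, paste(subject_id, visit_label)]]
  # keep subjects with at least one attended visit (baseline rate 0 ensures
  # this under defaults, but guard anyway)
  truth[, motor_bar := mean(motor_ij[attended]), by = subject_id]
  truth[, cog_bar := mean(cog_ij[attended]), by = subject_id]

  scored <- simulate_clinical_scores(truth[attended == TRUE], config)
  visits <- scored[, .(subject_id, visit_label, visit_date,
                       nhpt_t1, nhpt_t2, nhpt_t3, nhpt_t4,
                       sdmt_score, age, sex, education)]
  setorder(visits, subject_id, visit_date)

  # typing days: latent value of a day anchors to the nearest scheduled visit
  day_tbl <- .typing_days(truth, config)
  ev <- NULL
  daily <- NULL
  if (events) {
    ev <- .simulate_keys(day_tbl, config$typing)
  } else {
    daily <- .fast_daily_records(day_tbl, config)
  }

  out <- list(subjects = subjects[], visits = visits[], events = ev,
              daily = daily, ground_truth = truth[], config = config,
              seed = as.integer(seed))
  attr(out$ground_truth, "coefficients") <- list(
    nhpt = config$nhpt[c("beta_between", "beta_within")],
    sdmt = config$sdmt[c("beta_between", "beta_within")]
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(ev)) write_events(ev, file.path(out_dir, "events.csv"))
    data.table::fwrite(visits, file.path(out_dir, "visits.csv"))
    data.table::fwrite(
      truth[, .(subject_id, visit_label, visit_date, attended,
                motor_ij, cog_ij, motor_bar, cog_bar)],
      file.path(out_dir, "ground_truth.csv")
    )
  }
  out
}

# active typing days with day-level latent values and event counts
.typing_days <- function(truth, config) {
  half <- 14L # widest window
  day_list <- truth[, {
    last_day <- max(visit_day) # typing stops at the subject's final visit
    d <- if (config$days_mode == "windows") {
      unique(unlist(lapply(visit_day, function(v) seq(v - half, v + half))))
    } else {
      seq(0L, last_day)
    }
    d <- sort(d[d >= 0 & d <= last_day])
    # anchor each day to the nearest scheduled visit of the subject
    anchor <- vapply(d, function(x) which.min(abs(visit_day - x)), 1L)
    .(day = d, motor = motor_ij[anchor], cog = cog_ij[anchor])
  }, by = subject_id]
  active <- runif(nrow(day_list)) < config$adherence
  day_list <- day_list[active]
  epd <- config$events_per_day
  day_list[, n_events := pmax(2, round(.rlnorm_ms(.N, epd$mean, epd$sd)))]
  day_list[, `:=`(
    day_id = .I,
    date = config$study_start + day,
    n_keys = floor(n_events / 2),
    start_s = as.numeric(as.POSIXct(config$study_start, tz = "UTC")) +
      day * 86400 + 9 * 3600
  )]
  day_list[]
}

# fast path: daily feature records straight from latent states, with
# day-level noise mimicking the event path's per-day sampling error
.fast_daily_records <- function(day_tbl, config) {
  h <- config$typing$hold_mean
  n <- nrow(day_tbl)
  if (n == 0L) return(NULL)
  mot_noise <- rnorm(n, 0, 0.02)  # shared day-level motor noise
  cog_noise <- rnorm(n, 0, 0.10)
  feat <- list(
    PPL = day_tbl$motor + h / 3 + mot_noise + rnorm(n, 0, 0.005),
    RRL = day_tbl$motor + h / 3 + mot_noise + rnorm(n, 0, 0.005),
    FT = day_tbl$motor - 2 * h / 3 + mot_noise + rnorm(n, 0, 0.005),
    HT = h + rnorm(n, 0, 0.01),
    preCS = day_tbl$cog + cog_noise + rnorm(n, 0, 0.05),
    CD = 0.18 + rnorm(n, 0, 0.04),
    postCS = day_tbl$cog + cog_noise + rnorm(n, 0, 0.05),
    APP = day_tbl$cog + cog_noise + rnorm(n, 0, 0.05)
  )
  recs <- data.table::rbindlist(lapply(names(feat), function(ft) {
    data.table(subject_id = day_tbl$subject_id, date = day_tbl$date,
               feature = ft,
               n_samples = pmax(1L, round(day_tbl$n_events / 10)),
               daily_value = pmax(feat[[ft]], 0.01),
               day_event_count = day_tbl$n_events)
  }))
  recs[, feature := factor(feature, levels = kd_features())]
  setorder(recs, subject_id, date, feature)
  recs[]
}
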