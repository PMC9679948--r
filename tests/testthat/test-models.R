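mk_visits <- function(n_subj = 6, trials = NULL) {
  v <- expand.grid(subject_id = sprintf("P%02d", seq_len(n_subj)),
                   visit_label = c("M0", "M3"), stringsAsFactors = FALSE)
  v$visit_date <- as.Date("2020-01-01") + ifelse(v$visit_label == "M0", 0, 91)
  for (i in 1:4) v[[paste0("nhpt_t", i)]] <- 20 + i / 10
  v$sdmt_score <- 55L
  v$age <- 45
  v$sex <- "female"
  v$education <- "high"
  v
}

test_that("NHPT trials are averaged and outliers removed with counts", {
  v <- mk_visits(2)
  v[1, paste0("nhpt_t", 1:4)] <- c(20, 22, 21, 21)
  v[2, paste0("nhpt_t", 1:4)] <- c(44, 45, 46, 45)
  out <- prepare_visit_table(v, nhpt_outlier_s = 40)
  expect_equal(out[out$subject_id == "P01" & out$visit_label == "M0"]$nhpt_s,
               21.0)
  expect_true(is.na(out[out$subject_id == "P02" &
                          out$visit_label == "M0"]$nhpt_s))
  fl <- attr(out, "nhpt_outliers")
  expect_equal(fl$n_excluded, 1L)
  expect_equal(fl$n_total, 4L)
  # incomplete trials: NHPT missing with a warning
  v2 <- mk_visits(1)
  v2[1, "nhpt_t4"] <- NA
  expect_warning(out2 <- prepare_visit_table(v2), "4 NHPT trials")
  expect_true(is.na(out2$nhpt_s[1]))
})

test_that("visit table codes education, sex and days since baseline", {
  v <- mk_visits(2)
  v$education <- c("low", "middle", "high", "low")
  out <- prepare_visit_table(v)
  expect_s3_class(out$education, "factor")
  expect_equal(levels(out$education), c("low", "middle", "high"))
  expect_equal(out$days_since_baseline[out$visit_label == "M0"], c(0, 0))
  expect_equal(out$days_since_baseline[out$visit_label == "M3"], c(91, 91))
})

test_that("hybrid decomposition matches hand-computed values", {
  d <- data.frame(subject_id = c("a", "a", "a", "b"),
                  x = c(1, 2, 3, 7))
  h <- hybrid_decompose(d, "x")
  expect_equal(h$x_between, c(2, 2, 2, 7))
  expect_equal(h$x_within, c(-1, 0, 1, 0)) # single-visit subject: 0
})

test_that("hybrid deviations sum to zero within every subject", {
  set.seed(601)
  d <- data.frame(subject_id = rep(sprintf("s%02d", 1:30),
                                   times = sample(1:5, 30, replace = TRUE)))
  d$x <- rnorm(nrow(d))
  h <- hybrid_decompose(d, "x")
  sums <- as.numeric(tapply(h$x_within, h$subject_id, sum))
  expect_equal(sums, rep(0, length(sums)), tolerance = 1e-12)
  # shifting one subject's values moves only the between column
  d2 <- d
  d2$x[d2$subject_id == "s01"] <- d2$x[d2$subject_id == "s01"] + 10
  h2 <- hybrid_decompose(d2, "x")
  expect_equal(h2$x_within, h$x_within)
  expect_equal(h2$x_between[d$subject_id == "s01"],
               h$x_between[d$subject_id == "s01"] + 10)
})

test_that("with no between-subject heterogeneity the LMM slope matches OLS", {
  set.seed(602)
  n <- 400
  d <- data.frame(subject_id = rep(sprintf("s%02d", 1:40), each = 10),
                  x = rnorm(n))
  d$y <- 2 + 3 * d$x + rnorm(n, 0, 0.5)
  m <- suppressMessages(fit_random_intercept_lmm(d, "y", "x"))
  ols <- unname(coef(lm(y ~ x, d))["x"])
  expect_equal(m$fixed$estimate[m$fixed$term == "x"], ols, tolerance = 0.01)
  # CI brackets the estimate
  fx <- m$fixed[m$fixed$term == "x", ]
  expect_true(fx$ci_lo < fx$estimate && fx$estimate < fx$ci_hi)
})

test_that("the intercept-only model recovers the total variance", {
  set.seed(603)
  n_subj <- 200
  tau <- 2; sigma <- 1.5
  d <- data.frame(subject_id = rep(sprintf("s%03d", 1:n_subj), each = 4))
  d$y <- 10 + rep(rnorm(n_subj, 0, tau), each = 4) + rnorm(n_subj * 4, 0, sigma)
  m <- fit_random_intercept_lmm(d, "y")
  expect_equal(m$total_variance, tau^2 + sigma^2, tolerance = 0.15)
  expect_equal(m$n_subjects, n_subj)
  expect_equal(m$n_obs, n_subj * 4)
})

test_that("a predictor constant within subjects drops the within column", {
  d <- data.frame(subject_id = rep(c("a", "b", "c", "d"), each = 3))
  d$x <- rep(c(1, 2, 3, 4), each = 3)
  set.seed(604)
  d$y <- 5 + 2 * d$x + rnorm(12, 0, 0.1)
  expect_warning(
    m <- suppressMessages(fit_hybrid_lmm(d, "y", "x")),
    "inestimable"
  )
  expect_true(m$within_inestimable)
  expect_true(is.na(m$beta_within))
  expect_equal(m$beta_between, 2, tolerance = 0.1)
})

test_that("explained variance reproduces the reporting identities", {
  expect_equal(round(explained_variance(8, 13.7)), 42)
  expect_equal(round(explained_variance(82.7, 110.9), 1), 25.4)
  expect_equal(explained_variance(10, 10), 0)
  expect_warning(ev <- explained_variance(12, 10), "larger")
  expect_lt(ev, 0)
  expect_error(explained_variance(5, 0))
})

test_that("covariate relevance implements the 10% change-in-estimate rule", {
  expect_false(as.logical(covariate_relevance(12.62, 12.56)))
  expect_true(as.logical(covariate_relevance(-8.57, -5.02)))
  expect_true(as.logical(covariate_relevance(10, 9))) # exactly 10%: relevant
  expect_equal(attr(covariate_relevance(10, 9), "rel_change"), 0.1)
  expect_warning(r <- covariate_relevance(0, 1), "zero")
  expect_true(is.na(r))
})

test_that("SD scaling rounds to one decimal, two below magnitude one", {
  expect_equal(as.numeric(sd_scaled_effect(15.91, 0.16)), 2.5)
  expect_equal(as.numeric(sd_scaled_effect(6.94, 0.16)), 1.1)
  expect_equal(as.numeric(sd_scaled_effect(-11.25, 0.41)), -4.6)
  expect_equal(as.numeric(sd_scaled_effect(-0.35, 0.41)), -0.14)
  expect_equal(as.numeric(sd_scaled_effect(3, 0)), 0)
  expect_equal(sd_scaled_effect(15.91, 0.16, round_for_report = FALSE),
               2.5456)
  expect_error(sd_scaled_effect(1, -0.1))
})

test_that("the SDMT occasion intercept is a crossed random effect", {
  set.seed(605)
  co <- simulate_cohort(cohort_config(n_subjects = 40), seed = 71,
                        events = FALSE)
  gt <- co$ground_truth[co$ground_truth$attended == TRUE, ]
  vis <- prepare_visit_table(co$visits)
  m <- merge(vis, gt[, c("subject_id", "visit_label", "cog_ij")],
             by = c("subject_id", "visit_label"))
  fit <- suppressWarnings(
    fit_random_intercept_lmm(m, "sdmt_score", "cog_ij",
                             occasion_effect = TRUE)
  )
  expect_setequal(fit$var_components$grp,
                  c("subject_id", "visit_label", "Residual"))
  expect_gte(fit$total_variance, 0)
})
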