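test_that("perfectly collinear candidates are all retained", {
  x <- matrix(rnorm(300), ncol = 1)[, c(1, 1, 1)]
  colnames(x) <- c("f1", "f2", "f3")
  cs <- correlation_screen(x)
  expect_setequal(cs$retained, c("f1", "f2", "f3"))
})

test_that("an independent noise feature is dropped by both screens", {
  set.seed(501)
  n <- 500
  shared <- rnorm(n)
  x <- cbind(f1 = shared + rnorm(n, 0, 0.3),
             f2 = shared + rnorm(n, 0, 0.3),
             f3 = shared + rnorm(n, 0, 0.3),
             noise = rnorm(n))
  cs <- correlation_screen(x, r_min = 0.5)
  expect_setequal(cs$retained, c("f1", "f2", "f3"))
  ps <- pca_screen(x, tau = 0.7)
  expect_true(all(ps$pass[c("f1", "f2", "f3")]))
  expect_false(ps$pass[["noise"]])
})

test_that("a pair at exactly the threshold correlation is excluded", {
  # cor(x, y) is exactly 0.5 for these vectors
  x <- c(1, 2, 3)
  y <- c(1, 3, 2)
  expect_equal(cor(x, y), 0.5)
  cs <- correlation_screen(cbind(a = x, b = y), r_min = 0.5)
  expect_equal(length(cs$retained), 1L) # strict >: the pair does not cohere
})

test_that("constant columns are dropped with a warning", {
  x <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_warning(cs <- correlation_screen(x), "constant")
  expect_equal(cs$retained, "a")
  expect_error(correlation_screen(x[1:2, ]), "3 complete rows")
})

test_that("identical standardized features load equally and pass", {
  set.seed(502)
  z <- rnorm(100)
  x <- cbind(a = z, b = 2 * z + 1) # identical once standardized
  ps <- pca_screen(x)
  expect_equal(abs(ps$loadings[["a"]]), abs(ps$loadings[["b"]]),
               tolerance = 1e-10)
  expect_true(all(ps$pass))
})

test_that("a single candidate trivially passes the PCA screen", {
  ps <- pca_screen(matrix(rnorm(20), ncol = 1,
                          dimnames = list(NULL, "only")))
  expect_equal(abs(ps$loadings[["only"]]), 1)
  expect_true(ps$pass[["only"]])
})

test_that("screening outcomes are scale invariant and deterministic", {
  set.seed(503)
  n <- 300
  shared <- rnorm(n)
  x <- cbind(f1 = shared + rnorm(n, 0, 0.4),
             f2 = shared + rnorm(n, 0, 0.4),
             noise = rnorm(n))
  cs1 <- correlation_screen(x)
  cs2 <- correlation_screen(x * 1000) # seconds -> milliseconds
  expect_equal(cs2$retained, cs1$retained)
  ps1 <- pca_screen(x)
  ps2 <- pca_screen(x * 1000)
  expect_equal(ps2$pass, ps1$pass)
  expect_identical(correlation_screen(x)$retained, cs1$retained)
})

mk_daily_matrix <- function(n_days = 400, seed = 504) {
  # synthetic daily records: timing features share a motor driver (HT does
  # not), correction/punctuation pauses share a cognitive driver (CD does
  # not), mirroring the intended cluster structure
  set.seed(seed)
  motor <- rnorm(n_days, 0.43, 0.12)
  cog <- rnorm(n_days, 0.94, 0.35)
  vals <- data.frame(
    PPL = motor + rnorm(n_days, 0.03, 0.03),
    RRL = motor + rnorm(n_days, 0.03, 0.03),
    HT = rnorm(n_days, 0.09, 0.015),
    FT = motor - 0.06 + rnorm(n_days, 0, 0.03),
    preCS = cog + rnorm(n_days, 0, 0.12),
    CD = rnorm(n_days, 0.18, 0.05),
    postCS = cog + rnorm(n_days, 0, 0.12),
    APP = cog + rnorm(n_days, 0, 0.12)
  )
  do.call(rbind, lapply(names(vals), function(ft) {
    data.frame(subject_id = "A", date = as.Date("2020-01-01") + seq_len(n_days),
               feature = ft, n_samples = 10L, daily_value = vals[[ft]],
               day_event_count = 200L)
  }))
}

test_that("cluster construction reproduces the expected memberships", {
  daily <- mk_daily_matrix()
  defs <- build_cluster_definitions(daily)
  expect_setequal(defs$FMSC$members, c("PPL", "RRL", "FT"))
  expect_setequal(defs$CSC$members, c("preCS", "postCS", "APP"))
  expect_equal(defs$FMSC$window_half_width_days, 14)
  expect_equal(defs$CSC$window_half_width_days, 7)
})

test_that("mutually collinear candidates keep the full candidate set", {
  set.seed(505)
  motor <- rnorm(400, 0.43, 0.12)
  daily <- do.call(rbind, lapply(c("PPL", "RRL", "HT", "FT"), function(ft) {
    data.frame(subject_id = "A", date = as.Date("2020-01-01") + 1:400,
               feature = ft, n_samples = 10L,
               daily_value = motor + rnorm(400, 0, 0.01),
               day_event_count = 200L)
  }))
  cog <- rnorm(400, 0.9, 0.3)
  daily2 <- do.call(rbind, lapply(c("preCS", "CD", "postCS", "APP"),
                                  function(ft) {
    data.frame(subject_id = "A", date = as.Date("2020-01-01") + 1:400,
               feature = ft, n_samples = 10L,
               daily_value = cog + rnorm(400, 0, 0.01),
               day_event_count = 200L)
  }))
  defs <- build_cluster_definitions(rbind(daily, daily2))
  expect_setequal(defs$FMSC$members, c("PPL", "RRL", "HT", "FT"))
  expect_setequal(defs$CSC$members, c("preCS", "CD", "postCS", "APP"))
})

test_that("pinned memberships bypass the screens", {
  daily <- mk_daily_matrix(n_days = 30)
  pin <- list(FMSC = c("PPL", "RRL", "FT"), CSC = c("preCS", "postCS", "APP"))
  defs <- build_cluster_definitions(daily, pinned = pin)
  expect_equal(defs$FMSC$members, pin$FMSC)
  expect_equal(defs$CSC$members, pin$CSC)
  expect_true(defs$report$FMSC$pinned)
})

test_that("within-subject correlation scope ignores between-subject drivers", {
  set.seed(506)
  n_subj <- 40; n_day <- 30
  subj <- rep(sprintf("s%02d", seq_len(n_subj)), each = n_day)
  level <- rep(rnorm(n_subj, 1, 0.5), each = n_day) # shared subject level
  x <- cbind(f1 = level + rnorm(length(subj), 0, 0.1),
             f2 = level + rnorm(length(subj), 0, 0.1))
  # pooled: the subject level induces a strong correlation
  expect_setequal(correlation_screen(x)$retained, c("f1", "f2"))
  # within subjects the features are independent: the pair does not cohere
  cs_w <- correlation_screen(x, groups = subj)
  expect_equal(length(cs_w$retained), 1L)
  expect_lt(max(cs_w$correlations[upper.tri(cs_w$correlations)]), 0.5)
})

test_that("the within-subject scope reproduces memberships on cohort data", {
  co <- simulate_cohort(cohort_config(n_subjects = 25), seed = 507,
                        events = FALSE)
  defs <- build_cluster_definitions(co$daily,
                                    correlation_scope = "within_subject")
  expect_setequal(defs$FMSC$members, c("PPL", "RRL", "FT"))
  expect_setequal(defs$CSC$members, c("preCS", "postCS", "APP"))
})

test_that("cluster definitions validate their member sets", {
  expect_error(cluster_definition("FMSC", character(0), c("PPL"), 14))
  expect_error(cluster_definition("FMSC", "APP", c("PPL", "RRL"), 14))
  expect_error(cluster_definition("FMSC", "PPL", c("PPL"), -3))
  d <- cluster_definition("CSC", c("preCS", "postCS", "APP"),
                          c("preCS", "CD", "postCS", "APP"), 7)
  expect_s3_class(d, "cluster_definition")
  expect_output(print(d), "CSC")
})
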