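# Random-intercept and hybrid (between-/within-subject) linear mixed models.
#
# The overall association between a window cluster score X and a clinical
# outcome Y is estimated with Y = b0 + b1*X + covariates + u_subject + e,
# REML fit, Wald 95% CIs. The hybrid model splits X into the subject mean
# over modeled visits (between-subject column) and the per-visit deviation
# from that mean (within-subject column), whose coefficients are
# beta_between and beta_within. For outcomes with practice effects (SDMT), a
# crossed random intercept over the scheduled measurement occasion absorbs
# occasion-common score shifts.

#' Prepare the clinical visit table
#'
#' Averages the four NHPT trials into one score per visit, applies the
#' average-score outlier rule (scores above `nhpt_outlier_s` seconds are set
#' missing and counted), codes sex and the three-level education factor
#' (low/middle/high, unordered), and computes days since the subject's
#' baseline visit.
#'
#' @param visits Data frame with `subject_id`, `visit_label`, `visit_date`,
#'   either four trial columns `nhpt_t1`..`nhpt_t4` or a precomputed
#'   `nhpt_s`, plus `sdmt_score` (or `sdmt`), `age`, `sex`, `education`.
#' @param nhpt_outlier_s Outlier threshold on the averaged NHPT score in
#'   seconds (default 40).
#' @param baseline_label Visit label of the baseline visit (default `"M0"`).
#' @return A `data.table` of visit records; attribute `nhpt_outliers` carries
#'   `n_excluded`, `n_total` and `pct`.
#' @export
prepare_visit_table <- function(visits, nhpt_outlier_s = 40,
                                baseline_label = "M0") {
  stopifnot(is.numeric(nhpt_outlier_s), nhpt_outlier_s > 0)
  v <- as.data.table(visits)
  v[, subject_id := as.character(subject_id)]
  if ("sdmt" %in% names(v) && !"sdmt_score" %in% names(v)) {
    setnames(v, "sdmt", "sdmt_score")
  }
  trial_cols <- paste0("nhpt_t", 1:4)
  if (all(trial_cols %in% names(v))) {
    v[, nhpt_s := rowMeans(.SD), .SDcols = trial_cols]
    n_incomplete <- v[is.na(nhpt_s) &
                        rowSums(!is.na(v[, trial_cols, with = FALSE])) > 0, .N]
    if (n_incomplete > 0L) {
      warning(n_incomplete, " visit(s) with fewer than 4 NHPT trials: ",
              "NHPT set missing", call. = FALSE)
    }
  } else if (!"nhpt_s" %in% names(v)) {
    v[, nhpt_s := NA_real_]
    warning("no NHPT trials or precomputed average found; NHPT missing",
            call. = FALSE)
  }
  n_total <- sum(!is.na(v$nhpt_s))
  n_out <- sum(v$nhpt_s > nhpt_outlier_s, na.rm = TRUE)
  v[nhpt_s > nhpt_outlier_s, nhpt_s := NA_real_]
  if ("education" %in% names(v)) {
    v[, education := factor(as.character(education),
                            levels = c("low", "middle", "high"))]
  }
  if ("sex" %in% names(v)) v[, sex := factor(as.character(sex))]
  if ("visit_date" %in% names(v)) {
    v[, visit_date := as.Date(visit_date)]
    base <- v[visit_label == baseline_label,
              .(.base_date = visit_date[1L]), by = subject_id]
    v <- merge(v, base, by = "subject_id", all.x = TRUE)
    v[is.na(.base_date), .base_date := min(visit_date), by = subject_id]
    v[, days_since_baseline := as.numeric(visit_date - .base_date)]
    v[, .base_date := NULL]
  }
  if ("visit_label" %in% names(v)) {
    labs <- unique(v$visit_label)
    ord <- labs[order(suppressWarnings(as.numeric(gsub("\\D", "", labs))))]
    v[, visit_label := factor(visit_label, levels = ord)]
  }
  setorder(v, subject_id, visit_label)
  setattr(v, "nhpt_outliers",
          list(n_excluded = n_out, n_total = n_total,
               pct = rate_pct(n_out, max(n_total, 1L))))
  v[]
}

.fixed_effects_table <- function(fit) {
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- beta / se
  data.frame(
    term = names(beta),
    estimate = as.numeric(beta),
    se = as.numeric(se),
    ci_lo = as.numeric(beta - qnorm(0.975) * se),
    ci_hi = as.numeric(beta + qnorm(0.975) * se),
    p = as.numeric(2 * pnorm(-abs(z))),
    row.names = NULL
  )
}

#' Fit a random-intercept linear mixed model
#'
#' REML fit of `outcome ~ predictors + covariates + (1 | subject)`, with an
#' optional crossed random intercept over the measurement occasion
#' (`occasion_effect = TRUE`; used for SDMT to absorb practice effects common
#' to an occasion). Rows with missing values in any used variable are
#' excluded (complete-case per observation). Wald 95% CIs and p-values.
#'
#' @param data Data frame with one row per subject-visit.
#' @param outcome,predictors,covariates Column names (predictors/covariates
#'   may be empty for an intercept-only model).
#' @param subject Grouping column (default `"subject_id"`).
#' @param occasion_effect Add `(1 | occasion)` (default `FALSE`).
#' @param occasion Occasion column (default `"visit_label"`).
#' @param reml Use REML (default `TRUE`).
#' @return A `mixed_model_result`: list with the `lme4` fit, the fixed-effect
#'   table (`fixed`), `total_variance` (sum of random-effect and residual
#'   variances), `var_components`, `n_subjects`, `n_obs`, `singular`.
#' @export
fit_random_intercept_lmm <- function(data, outcome, predictors = character(),
                                     covariates = character(),
                                     subject = "subject_id",
                                     occasion_effect = FALSE,
                                     occasion = "visit_label",
                                     reml = TRUE) {
  used <- c(outcome, predictors, covariates, subject,
            if (occasion_effect) occasion)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0L) {
    stop("model variables not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dd <- as.data.frame(data)[, used, drop = FALSE]
  dd <- dd[complete.cases(dd), , drop = FALSE]
  if (length(unique(dd[[subject]])) < 2L) {
    stop("need >= 2 subjects with observations", call. = FALSE)
  }
  rhs <- c(if (length(c(predictors, covariates)) > 0)
    c(predictors, covariates) else "1",
    sprintf("(1 | %s)", subject),
    if (occasion_effect) sprintf("(1 | %s)", occasion))
  fml <- as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  fit <- tryCatch(
    lme4::lmer(fml, data = dd, REML = reml,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    error = function(e) {
      stop("mixed model failed to converge: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  res <- structure(
    list(
      fit = fit,
      formula = deparse(fml),
      outcome = outcome,
      fixed = .fixed_effects_table(fit),
      total_variance = sum(vc$vcov),
      var_components = vc[, c("grp", "vcov")],
      n_subjects = length(unique(dd[[subject]])),
      n_obs = nrow(dd),
      singular = lme4::isSingular(fit)
    ),
    class = "mixed_model_result"
  )
  res
}

#' @export
print.mixed_model_result <- function(x, digits = 3, ...) {
  cat("Linear mixed model (REML):", x$formula, "\n")
  cat(sprintf("  %d observations, %d subjects%s\n", x$n_obs, x$n_subjects,
              if (isTRUE(x$singular)) " (singular fit)" else ""))
  fx <- x$fixed
  fx[, -1] <- lapply(fx[, -1], round, digits)
  print(fx, row.names = FALSE)
  cat(sprintf("  total random-effect + residual variance: %.*f\n",
              digits, x$total_variance))
  invisible(x)
}

#' Person-mean centering for the hybrid model
#'
#' Adds `<var>_between` (the subject's mean of `var` over its non-missing
#' rows) and `<var>_within` (the per-row deviation from that mean). The
#' deviations of every subject sum to zero exactly; adding a constant to one
#' subject's values moves only the between column.
#'
#' @param data Data frame.
#' @param var Predictor column to decompose.
#' @param subject Grouping column.
#' @return `data` with the two added columns.
#' @export
hybrid_decompose <- function(data, var, subject = "subject_id") {
  stopifnot(var %in% names(data), subject %in% names(data))
  dd <- as.data.frame(data)
  xb <- ave(dd[[var]], dd[[subject]],
            FUN = function(v) mean(v, na.rm = TRUE))
  dd[[paste0(var, "_between")]] <- xb
  dd[[paste0(var, "_within")]] <- dd[[var]] - xb
  dd
}

#' Fit the hybrid between-/within-subject mixed model
#'
#' Decomposes the predictor into subject means and deviations on the modeled
#' (complete-case) rows, then fits
#' `outcome ~ X_between + X_within + covariates + (1 | subject)` (plus the
#' occasion intercept when requested). If the predictor is constant within
#' every subject the within column is inestimable and dropped with a warning.
#'
#' @inheritParams fit_random_intercept_lmm
#' @param predictor Name of the cluster-score column to decompose.
#' @return A `hybrid_model_result` (also a `mixed_model_result`) with
#'   `beta_between` and `beta_within` rows in `fixed` and convenience fields
#'   `beta_between`, `beta_within`, `within_inestimable`.
#' @export
fit_hybrid_lmm <- function(data, outcome, predictor, covariates = character(),
                           subject = "subject_id", occasion_effect = FALSE,
                           occasion = "visit_label", reml = TRUE) {
  used <- c(outcome, predictor, covariates, subject,
            if (occasion_effect) occasion)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0L) {
    stop("model variables not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dd <- as.data.frame(data)[, used, drop = FALSE]
  dd <- dd[complete.cases(dd), , drop = FALSE]
  dd <- hybrid_decompose(dd, predictor, subject)
  bcol <- paste0(predictor, "_between")
  wcol <- paste0(predictor, "_within")
  within_ok <- max(abs(dd[[wcol]])) > 1e-10
  if (!within_ok) {
    warning("predictor is constant within every subject: within-subject ",
            "effect inestimable, deviation column dropped", call. = FALSE)
  }
  preds <- c(bcol, if (within_ok) wcol)
  res <- fit_random_intercept_lmm(dd, outcome, predictors = preds,
                                  covariates = covariates, subject = subject,
                                  occasion_effect = occasion_effect,
                                  occasion = occasion, reml = reml)
  res$predictor <- predictor
  res$beta_between <- res$fixed$estimate[res$fixed$term == bcol]
  res$beta_within <- if (within_ok)
    res$fixed$estimate[res$fixed$term == wcol] else NA_real_
  res$within_inestimable <- !within_ok
  class(res) <- c("hybrid_model_result", class(res))
  res
}

#' Explained variance relative to the intercept-only model
#'
#' Proportional reduction of total (random-effect + residual) variance:
#' `100 * (V0 - V_model) / V0`.
#'
#' @param v_model Total variance of the fitted model.
#' @param v_intercept_only Total variance of the intercept-only model (> 0).
#' @return Percentage (may be negative, with a warning, if the model
#'   increased the total variance).
#' @examples
#' explained_variance(8, 13.7)      # ~41.6
#' explained_variance(82.7, 110.9)  # ~25.4
#' @export
explained_variance <- function(v_model, v_intercept_only) {
  stopifnot(is.numeric(v_model), is.numeric(v_intercept_only),
            v_intercept_only > 0)
  ev <- 100 * (v_intercept_only - v_model) / v_intercept_only
  if (any(ev < 0)) {
    warning("model has larger total variance than the intercept-only model",
            call. = FALSE)
  }
  ev
}

#' Change-in-estimate covariate relevance
#'
#' Covariates are flagged as relevant when the effect estimate changes by at
#' least `threshold` (default 10%) after their inclusion:
#' `|beta_adjusted - beta_crude| / |beta_crude| >= threshold`.
#'
#' @param beta_crude Estimate without covariates (nonzero).
#' @param beta_adjusted Estimate with covariates.
#' @param threshold Relative-change threshold (default 0.10).
#' @return Logical flag with attribute `rel_change`; `NA` (with a warning)
#'   when `beta_crude` is zero.
#' @export
covariate_relevance <- function(beta_crude, beta_adjusted, threshold = 0.10) {
  stopifnot(is.numeric(beta_crude), is.numeric(beta_adjusted),
            threshold >= 0)
  if (beta_crude == 0) {
    warning("relative change undefined for a zero crude estimate",
            call. = FALSE)
    return(structure(NA, rel_change = NA_real_))
  }
  rel <- abs(beta_adjusted - beta_crude) / abs(beta_crude)
  structure(rel >= threshold, rel_change = rel)
}

#' Effect size per 1 SD of the predictor
#'
#' Rescales a regression coefficient to the outcome change corresponding to
#' a one-SD change in the predictor (`beta * sd`). For reporting, the value
#' is rounded to one decimal, or two when its magnitude is below 1.
#'
#' @param beta Coefficient (outcome units per predictor unit).
#' @param sd_of_predictor SD of the predictor (>= 0).
#' @param round_for_report Apply the reporting rounding (default `TRUE`).
#' @return The scaled effect; the unrounded value is kept in attribute
#'   `raw` when rounding is applied.
#' @examples
#' sd_scaled_effect(15.91, 0.16) # 2.5
#' sd_scaled_effect(-0.35, 0.41) # -0.14
#' @export
sd_scaled_effect <- function(beta, sd_of_predictor, round_for_report = TRUE) {
  stopifnot(is.numeric(beta), is.numeric(sd_of_predictor),
            sd_of_predictor >= 0)
  raw <- beta * sd_of_predictor
  if (!round_for_report) return(raw)
  out <- if (abs(raw) < 1) round(raw, 2) else round(raw, 1)
  structure(out, raw = raw)
}
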