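# End-to-end orchestration: ingest -> sessions -> features -> daily records
# -> cluster construction -> window scores -> mixed models -> report.

#' Pipeline configuration
#'
#' All thresholds of the analysis live here; none are hidden in the stages.
#'
#' @param min_events Daily raw-event threshold (default 50).
#' @param nhpt_outlier_s NHPT average-score outlier threshold in seconds
#'   (default 40).
#' @param r_min Correlation-screen threshold (strict `>`; default 0.50).
#' @param tau PCA-screen relative loading threshold (default 0.7).
#' @param max_gap_s Session gap bound in seconds (default 5).
#' @param fmsc_half_width,csc_half_width Visit-window half-widths in days
#'   (defaults 14 and 7).
#' @param nhpt_covariates Covariates of the NHPT models (default age, sex).
#' @param sdmt_covariates Covariates of the SDMT models (default age, sex,
#'   education).
#' @param sdmt_occasion_effect Crossed random intercept over occasion in the
#'   SDMT models (default `TRUE`; absorbs practice effects).
#' @param pinned_memberships Optional fixed cluster memberships (bypasses the
#'   screens), e.g. `list(FMSC = c("PPL","RRL","FT"),
#'   CSC = c("preCS","postCS","APP"))`.
#' @param averaging_order `"daily_first"` (default) or `"feature_first"`; see
#'   [cluster_window_scores()].
#' @param cap_s Optional per-sample cap in seconds (default off).
#' @param tz Timezone for dating events.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(min_events = 50, nhpt_outlier_s = 40,
                            r_min = 0.50, tau = 0.7, max_gap_s = 5.0,
                            fmsc_half_width = 14, csc_half_width = 7,
                            nhpt_covariates = c("age", "sex"),
                            sdmt_covariates = c("age", "sex", "education"),
                            sdmt_occasion_effect = TRUE,
                            pinned_memberships = NULL,
                            averaging_order = c("daily_first",
                                                "feature_first"),
                            cap_s = NULL, tz = "UTC") {
  averaging_order <- match.arg(averaging_order)
  stopifnot(min_events >= 1, nhpt_outlier_s > 0,
            r_min >= -1, r_min <= 1, tau > 0, tau <= 1, max_gap_s >= 0,
            fmsc_half_width >= 0, csc_half_width >= 0)
  structure(
    list(min_events = min_events, nhpt_outlier_s = nhpt_outlier_s,
         r_min = r_min, tau = tau, max_gap_s = max_gap_s,
         fmsc_half_width = fmsc_half_width, csc_half_width = csc_half_width,
         nhpt_covariates = nhpt_covariates,
         sdmt_covariates = sdmt_covariates,
         sdmt_occasion_effect = sdmt_occasion_effect,
         pinned_memberships = pinned_memberships,
         averaging_order = averaging_order, cap_s = cap_s, tz = tz),
    class = "pipeline_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

# one outcome's model ladder: intercept-only, cluster, cluster+covariates,
# hybrid (with covariates)
.model_ladder <- function(data, outcome, predictor, covariates,
                          occasion_effect) {
  m0 <- fit_random_intercept_lmm(data, outcome,
                                 occasion_effect = occasion_effect)
  m1 <- fit_random_intercept_lmm(data, outcome, predictors = predictor,
                                 occasion_effect = occasion_effect)
  m2 <- fit_random_intercept_lmm(data, outcome, predictors = predictor,
                                 covariates = covariates,
                                 occasion_effect = occasion_effect)
  m3 <- fit_hybrid_lmm(data, outcome, predictor, covariates = covariates,
                       occasion_effect = occasion_effect)
  v0 <- m0$total_variance
  beta_of <- function(m, term) {
    i <- match(term, m$fixed$term)
    m$fixed[i, c("estimate", "ci_lo", "ci_hi", "p")]
  }
  row <- function(model_name, term_name, m, term) {
    b <- beta_of(m, term)
    data.frame(model = model_name, term = term_name,
               beta = b$estimate, ci_lo = b$ci_lo, ci_hi = b$ci_hi, p = b$p,
               total_variance = m$total_variance,
               explained_pct = explained_variance(m$total_variance, v0))
  }
  tbl <- rbind(
    data.frame(model = "intercept_only", term = NA_character_,
               beta = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
               p = NA_real_, total_variance = v0, explained_pct = 0),
    row("cluster", predictor, m1, predictor),
    row("cluster_covariates", predictor, m2, predictor),
    row("hybrid", "between", m3, paste0(predictor, "_between")),
    row("hybrid", "within", m3, paste0(predictor, "_within"))
  )
  crude <- m1$fixed$estimate[m1$fixed$term == predictor]
  adj <- m2$fixed$estimate[m2$fixed$term == predictor]
  rel <- covariate_relevance(crude, adj)
  list(table = tbl, fits = list(intercept_only = m0, cluster = m1,
                                cluster_covariates = m2, hybrid = m3),
       covariates_relevant = as.logical(rel),
       covariate_rel_change = as.numeric(attr(rel, "rel_change")),
       sd_predictor = sd(data[[predictor]], na.rm = TRUE))
}

.descriptives <- function(visits, scores) {
  v <- as.data.table(visits)
  out_v <- v[, .(
    n_nhpt = sum(!is.na(nhpt_s)),
    nhpt_median = as.numeric(median(nhpt_s, na.rm = TRUE)),
    nhpt_iqr_lo = as.numeric(quantile(nhpt_s, 0.25, na.rm = TRUE)),
    nhpt_iqr_hi = as.numeric(quantile(nhpt_s, 0.75, na.rm = TRUE)),
    n_sdmt = sum(!is.na(sdmt_score)),
    sdmt_mean = mean(sdmt_score, na.rm = TRUE),
    sdmt_sd = sd(sdmt_score, na.rm = TRUE)
  ), by = visit_label]
  s <- as.data.table(scores)
  out_s <- s[, .(n = .N, mean_s = mean(value), sd_s = sd(value),
                 days_mean = mean(n_days), days_sd = sd(n_days)),
             by = .(cluster, visit_label)]
  list(outcomes = out_v[], clusters = out_s[])
}

#' Run the full keystroke-dynamics analysis pipeline
#'
#' Ingests events and visits (paths or data frames), derives features, daily
#' records and visit-window cluster scores, constructs (or pins) the cluster
#' definitions, fits the model ladder for both outcomes (intercept-only,
#' cluster, cluster + covariates, hybrid between/within) and assembles a
#' reproducible report. Any stage failure aborts with a stage-named error.
#'
#' @param events Event table or path to an events CSV.
#' @param visits Visit table (with NHPT trials, SDMT, covariates) or path to
#'   a visits CSV.
#' @param config A [pipeline_config()].
#' @param seed Seed recorded in the provenance block (the analysis itself is
#'   deterministic).
#' @return A `keytype_report` list: `cluster_definitions`, `scores`, `daily`,
#'   `models` (per outcome: table, fits, covariate relevance, SD-scaled
#'   effects), `model_table` (both outcomes stacked), `descriptives`,
#'   `filtering` counts, `provenance`.
#' @export
run_pipeline <- function(events, visits, config = pipeline_config(),
                         seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ev <- .stage("ingest", {
    if (is.character(events)) read_events(events) else as.data.table(events)
  })
  vis <- .stage("visits", {
    raw <- if (is.character(visits)) data.table::fread(visits) else visits
    prepare_visit_table(raw, nhpt_outlier_s = config$nhpt_outlier_s)
  })
  sess <- .stage("sessions",
                 segment_sessions(ev, max_gap_s = config$max_gap_s,
                                  tz = config$tz))
  samples <- .stage("features",
                    extract_features(sess, tz = config$tz,
                                     cap_s = config$cap_s))
  daily <- .stage("aggregate_daily",
                  aggregate_daily(samples, ev,
                                  min_events = config$min_events,
                                  tz = config$tz))
  all_days <- as.data.table(sess)[, .(n = .N),
                                  by = .(subject_id,
                                         date = ms_to_date(timestamp_ms,
                                                           config$tz))]
  days_dropped <- all_days[n < config$min_events, .N]
  defs <- .stage("clusters",
                 build_cluster_definitions(
                   daily, r_min = config$r_min, tau = config$tau,
                   pinned = config$pinned_memberships,
                   fmsc_half_width = config$fmsc_half_width,
                   csc_half_width = config$csc_half_width))
  scores <- .stage("window_scores",
                   cluster_window_scores(daily, vis,
                                         defs[c("FMSC", "CSC")],
                                         order = config$averaging_order))
  models <- .stage("models", {
    sc_w <- data.table::dcast(scores, subject_id + visit_label ~ cluster,
                              value.var = "value")
    mdat <- merge(vis, sc_w, by = c("subject_id", "visit_label"),
                  all.x = TRUE)
    nhpt <- if ("FMSC" %in% names(sc_w))
      .model_ladder(mdat[!is.na(mdat$FMSC) & !is.na(mdat$nhpt_s)],
                    "nhpt_s", "FMSC", config$nhpt_covariates,
                    occasion_effect = FALSE) else NULL
    sdmt <- if ("CSC" %in% names(sc_w))
      .model_ladder(mdat[!is.na(mdat$CSC) & !is.na(mdat$sdmt_score)],
                    "sdmt_score", "CSC", config$sdmt_covariates,
                    occasion_effect = config$sdmt_occasion_effect) else NULL
    list(nhpt = nhpt, sdmt = sdmt)
  })
  for (oc in names(models)) {
    if (is.null(models[[oc]])) next
    hy <- models[[oc]]$fits$hybrid
    models[[oc]]$sd_scaled <- list(
      between = sd_scaled_effect(hy$beta_between, models[[oc]]$sd_predictor),
      within = sd_scaled_effect(hy$beta_within, models[[oc]]$sd_predictor)
    )
  }
  model_table <- data.table::rbindlist(
    lapply(names(models), function(oc) {
      if (is.null(models[[oc]])) return(NULL)
      cbind(outcome = oc, models[[oc]]$table)
    })
  )
  outliers <- attr(vis, "nhpt_outliers")
  report <- structure(list(
    cluster_definitions = defs[c("FMSC", "CSC")],
    cluster_report = defs$report,
    daily = daily,
    scores = scores,
    visits = vis,
    models = models,
    model_table = model_table,
    descriptives = .descriptives(vis, scores),
    filtering = list(
      rejected_event_rows = attr(ev, "n_rejected") %||% 0L,
      days_below_event_threshold = days_dropped,
      nhpt_outliers = outliers
    ),
    provenance = list(
      package = "keytype",
      version = as.character(utils::packageVersion("keytype")),
      seed = seed,
      config = unclass(config),
      config_hash = .config_hash(config)
    )
  ), class = "keytype_report")
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' @export
print.keytype_report <- function(x, ...) {
  cat("keystroke-dynamics analysis report\n")
  for (cl in names(x$cluster_definitions)) print(x$cluster_definitions[[cl]])
  cat(sprintf("filtering: %d event rows rejected; %d days below threshold; %d/%d NHPT outliers (%.1f%%)\n",
              x$filtering$rejected_event_rows,
              x$filtering$days_below_event_threshold,
              x$filtering$nhpt_outliers$n_excluded,
              x$filtering$nhpt_outliers$n_total,
              x$filtering$nhpt_outliers$pct))
  mt <- as.data.frame(x$model_table)
  num <- vapply(mt, is.numeric, logical(1))
  mt[num] <- lapply(mt[num], round, 3)
  print(mt, row.names = FALSE)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes a machine-readable JSON mirroring the human-readable CSVs
#' field-for-field. Numbers are serialized at full precision; rounding is a
#' display concern only.
#'
#' @param report A `keytype_report` from [run_pipeline()], or a partial list
#'   with any of its table fields.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  ok <- tryCatch({
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    dir.exists(dir)
  }, error = function(e) FALSE)
  if (!ok) stop("cannot create report directory: ", dir, call. = FALSE)
  model_table <- as.data.frame(report$model_table %||%
                                 data.frame())
  desc_out <- as.data.frame(report$descriptives$outcomes %||% data.frame())
  desc_cl <- as.data.frame(report$descriptives$clusters %||% data.frame())
  scores <- as.data.frame(report$scores %||% data.frame())
  defs <- lapply(report$cluster_definitions %||% list(), function(d) {
    list(name = d$name, members = d$members, candidates = d$candidates,
         window_half_width_days = d$window_half_width_days)
  })
  payload <- list(
    cluster_definitions = defs,
    model_table = model_table,
    descriptives = list(outcomes = desc_out, clusters = desc_cl),
    window_scores = scores,
    filtering = report$filtering,
    provenance = report$provenance
  )
  paths <- c(
    json = file.path(dir, "report.json"),
    model_table = file.path(dir, "model_table.csv"),
    descriptives_outcomes = file.path(dir, "descriptives_outcomes.csv"),
    descriptives_clusters = file.path(dir, "descriptives_clusters.csv"),
    window_scores = file.path(dir, "window_scores.csv")
  )
  jsonlite::write_json(payload, paths["json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  data.table::fwrite(model_table, paths["model_table"])
  data.table::fwrite(desc_out, paths["descriptives_outcomes"])
  data.table::fwrite(desc_cl, paths["descriptives_clusters"])
  data.table::fwrite(scores, paths["window_scores"])
  invisible(paths)
}
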