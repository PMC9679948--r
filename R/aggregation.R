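# Daily aggregation and visit-window cluster scores.
#
# Scheme: per subject/day/feature, the daily value is the average of the
# day's sample mean and sample median (both summarize the latency
# distribution on the seconds scale; averaging them avoids carrying two
# collinear summaries forward). Days with fewer than `min_events` raw
# press/release events are removed entirely. Daily cluster values are the
# unweighted mean of the member features' daily values, and visit-window
# scores are the mean of the daily cluster values over +/- half_width
# calendar days around the visit (inclusive of the visit day).

#' Collapse feature samples into daily records
#'
#' @param samples Feature samples from [extract_features()].
#' @param events Raw event table ([read_events()] output); used to count the
#'   day's press+release events for the event-count threshold. Alternatively
#'   a precomputed count table with columns `subject_id`, `date`,
#'   `day_event_count`.
#' @param min_events Minimum raw keystroke events per day (default 50): days
#'   below the threshold emit no records at all.
#' @param tz Timezone for dating events.
#' @return `data.table` with `subject_id`, `date`, `feature`, `n_samples`,
#'   `daily_value`, `day_event_count`.
#' @export
aggregate_daily <- function(samples, events, min_events = 50, tz = "UTC") {
  if (!is.numeric(min_events) || length(min_events) != 1L || min_events < 1) {
    stop("min_events must be a single count >= 1", call. = FALSE)
  }
  ev <- as.data.table(events)
  if ("day_event_count" %in% names(ev)) {
    counts <- ev[, .(subject_id, date, day_event_count)]
  } else {
    counts <- ev[, .(day_event_count = .N),
                 by = .(subject_id, date = ms_to_date(timestamp_ms, tz = tz))]
  }
  keep <- counts[day_event_count >= min_events]
  sm <- as.data.table(samples)
  # mean and median kept GForce-optimizable; combined afterwards
  rec <- sm[, .(n_samples = .N, .m = mean(value_s), .md = median(value_s)),
            by = .(subject_id, date, feature)]
  rec[, daily_value := (.m + .md) / 2]
  rec[, c(".m", ".md") := NULL]
  out <- merge(rec, keep, by = c("subject_id", "date"))
  setorder(out, subject_id, date, feature)
  out[]
}

#' Daily cluster value from daily feature records
#'
#' Unweighted mean of the member features' daily values for each subject-day;
#' days on which no member feature has a record emit no value.
#'
#' @param daily Daily records from [aggregate_daily()].
#' @param cluster_def A [cluster_definition()].
#' @return `data.table` with `subject_id`, `date`, `value`, `n_features`.
#' @export
cluster_daily_score <- function(daily, cluster_def) {
  stopifnot(inherits(cluster_def, "cluster_definition"))
  dt <- as.data.table(daily)
  out <- dt[feature %in% cluster_def$members,
            .(value = mean(daily_value), n_features = .N),
            by = .(subject_id, date)]
  setorder(out, subject_id, date)
  out[]
}

#' Aggregate daily cluster values over visit windows
#'
#' For each subject and visit, the window score is the mean of the daily
#' cluster values on days within `half_width_days` calendar days of the visit
#' date (inclusive on both sides, so a half-width of 14 admits up to 29
#' days). Visits with no contributing day yield no row: the visit is then
#' excluded pairwise from any model using that cluster.
#'
#' @param daily_cluster Output of [cluster_daily_score()].
#' @param visits Data frame with `subject_id`, `visit_label`, `visit_date`.
#' @param half_width_days Window half-width in days (14 for FMSC, 7 for CSC).
#' @param cluster_name Label stored in the `cluster` column.
#' @return `data.table` with `subject_id`, `visit_label`, `cluster`, `value`,
#'   `n_days`.
#' @export
window_aggregate <- function(daily_cluster, visits, half_width_days,
                             cluster_name = "cluster") {
  stopifnot(is.numeric(half_width_days), half_width_days >= 0)
  vis <- unique(as.data.table(visits)[, .(subject_id = as.character(subject_id),
                                          visit_label, visit_date)])
  dc <- as.data.table(daily_cluster)
  j <- merge(dc, vis, by = "subject_id", allow.cartesian = TRUE)
  j <- j[abs(as.numeric(date - visit_date)) <= half_width_days]
  out <- j[, .(cluster = cluster_name, value = mean(value), n_days = .N),
           by = .(subject_id, visit_label)]
  setorder(out, subject_id, visit_label)
  out[]
}

#' Visit-window scores for both keystroke clusters
#'
#' Runs the daily-cluster and window aggregation for each cluster definition.
#' Two averaging orders are available: `"daily_first"` (default) computes a
#' daily cluster mean and then averages days, weighting every day equally;
#' `"feature_first"` computes per-feature window means first and then
#' averages features, which differs when member features have unequal day
#' coverage (kept as a sensitivity analysis).
#'
#' @param daily Daily records from [aggregate_daily()].
#' @param visits Data frame with `subject_id`, `visit_label`, `visit_date`.
#' @param cluster_defs List of [cluster_definition()]s, e.g. from
#'   [build_cluster_definitions()].
#' @param order `"daily_first"` or `"feature_first"`.
#' @return `data.table` with `subject_id`, `visit_label`, `cluster`, `value`,
#'   `n_days`.
#' @export
cluster_window_scores <- function(daily, visits, cluster_defs,
                                  order = c("daily_first", "feature_first")) {
  order <- match.arg(order)
  out <- lapply(cluster_defs, function(def) {
    if (order == "daily_first") {
      window_aggregate(cluster_daily_score(daily, def), visits,
                       def$window_half_width_days, def$name)
    } else {
      dt <- as.data.table(daily)[feature %in% def$members]
      feats <- lapply(def$members, function(ft) {
        sub <- dt[feature == ft, .(subject_id, date, value = daily_value)]
        w <- window_aggregate(sub, visits, def$window_half_width_days, def$name)
        w[, feature := ft]
        w
      })
      fw <- data.table::rbindlist(feats)
      fw[, .(cluster = def$name, value = mean(value), n_days = max(n_days)),
         by = .(subject_id, visit_label)]
    }
  })
  data.table::rbindlist(out)[]
}
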