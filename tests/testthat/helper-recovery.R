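# end-to-end parameter recovery: events -> features -> daily records ->
# cluster screens -> window scores -> hybrid mixed models, repeated over
# independently seeded cohorts
recovery_replicate <- function(seed,
                               events_per_day = list(mean = 60, sd = 10)) {
  cfg <- cohort_config(events_per_day = events_per_day)
  co <- simulate_cohort(cfg, seed = seed)
  sess <- segment_sessions(co$events, max_gap_s = 5)
  daily <- aggregate_daily(extract_features(sess), co$events, min_events = 50)
  defs <- build_cluster_definitions(daily)
  scores <- cluster_window_scores(daily, co$visits, defs[c("FMSC", "CSC")])
  wide <- data.table::dcast(scores, subject_id + visit_label ~ cluster,
                            value.var = "value")
  vis <- prepare_visit_table(co$visits)
  mdat <- merge(vis, wide, by = c("subject_id", "visit_label"), all.x = TRUE)
  h_n <- fit_hybrid_lmm(mdat, "nhpt_s", "FMSC", c("age", "sex"))
  h_s <- suppressWarnings(
    fit_hybrid_lmm(mdat, "sdmt_score", "CSC", c("age", "sex", "education"),
                   occasion_effect = TRUE)
  )
  ci <- function(m, term) {
    i <- match(term, m$fixed$term)
    c(m$fixed$ci_lo[i], m$fixed$ci_hi[i])
  }
  c(nhpt_between = h_n$beta_between, nhpt_within = h_n$beta_within,
    sdmt_between = h_s$beta_between, sdmt_within = h_s$beta_within,
    nb_ci = ci(h_n, "FMSC_between"), nw_ci = ci(h_n, "FMSC_within"),
    sb_ci = ci(h_s, "CSC_between"), sw_ci = ci(h_s, "CSC_within"),
    fmsc_members = length(defs$FMSC$members),
    csc_members = length(defs$CSC$members))
}

recovery_truth <- function() {
  cfg <- cohort_config()
  c(nhpt_between = cfg$nhpt$beta_between, nhpt_within = cfg$nhpt$beta_within,
    sdmt_between = cfg$sdmt$beta_between, sdmt_within = cfg$sdmt$beta_within)
}

recovery_study <- function(n_reps, seed_base,
                           events_per_day = list(mean = 60, sd = 10)) {
  t(vapply(seq_len(n_reps),
           function(i) recovery_replicate(seed_base + i, events_per_day),
           numeric(14)))
}
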