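# Keystroke-dynamics feature extraction.
#
# Events are first collapsed to key *instances* (one press paired with its
# release via key_token, ordered by press time within a session). Features:
#   HT   hold time                release(k) - press(k), alphanumeric keys
#   PPL  press-press latency      press(k+1) - press(k)   } adjacent
#   RRL  release-release latency  release(k+1)-release(k) } alphanumeric
#   FT   flight time              press(k+1) - release(k) } instances
#   preCS/CD/postCS  pause before / span of / pause after a maximal run of
#                    backspace keys (a correction burst)
#   APP  press(next key) - release(punctuation key)
# PPL/RRL/FT require the two alphanumeric instances to be adjacent in the
# instance sequence: a pair interrupted by a key of another class yields no
# sample. Flight time may be negative under rollover typing and is retained.
# Every sample is dated by the calendar date of its first contributing event.

# press/release pairing: k-th press of a key_token within a session is
# matched to the k-th release of the same token; releases preceding their
# press are discarded (tallied), presses without a release are kept
# unmatched (hold-based features simply have no sample for them).
# Lead (next-instance) columns are added in the same pass.
.key_instances <- function(sessions) {
  ev <- as.data.table(sessions)
  p <- ev[action == "press",
          .(subject_id, session_id, key_token, key_class,
            press_ms = timestamp_ms)]
  p[, k := data.table::rowid(session_id, key_token)]
  r <- ev[action == "release",
          .(session_id, key_token, release_ms = timestamp_ms)]
  r[, k := data.table::rowid(session_id, key_token)]
  inst <- merge(p, r, by = c("session_id", "key_token", "k"), all.x = TRUE)
  n_inverted <- inst[!is.na(release_ms) & release_ms < press_ms, .N]
  inst[!is.na(release_ms) & release_ms < press_ms, release_ms := NA_real_]
  setorder(inst, session_id, press_ms)
  inst[, pos := data.table::rowid(session_id)]
  inst[, c("nxt_key_class", "nxt_press_ms", "nxt_release_ms") :=
         shift(.SD, type = "lead"), by = session_id,
       .SDcols = c("key_class", "press_ms", "release_ms")]
  setattr(inst, "n_discarded_pairs", n_inverted)
  inst[]
}

# raw sample block: dates converted once at assembly time
.samples <- function(subject_id, ms_first, feature, value_ms) {
  data.table(subject_id = subject_id, ms_first = ms_first,
             feature = feature, value_ms = value_ms)
}

.finish_samples <- function(blocks, tz, cap_s = NULL) {
  out <- data.table::rbindlist(blocks)
  if (nrow(out) == 0L) {
    return(data.table(subject_id = character(), date = as.Date(character()),
                      feature = character(), value_s = numeric()))
  }
  out[, `:=`(date = ms_to_date(ms_first, tz = tz), value_s = value_ms / 1000)]
  out[, c("ms_first", "value_ms") := NULL]
  setcolorder(out, c("subject_id", "date", "feature", "value_s"))
  if (!is.null(cap_s)) {
    stopifnot(is.numeric(cap_s), cap_s > 0)
    out <- out[value_s <= cap_s]
  }
  out[]
}

.timing_blocks <- function(inst) {
  an <- inst[key_class == "alphanumeric" & !is.na(release_ms)]
  ht <- .samples(an$subject_id, an$press_ms, "HT",
                 an$release_ms - an$press_ms)
  pair <- inst[key_class == "alphanumeric" &
                 nxt_key_class == "alphanumeric"]
  ppl <- .samples(pair$subject_id, pair$press_ms, "PPL",
                  pair$nxt_press_ms - pair$press_ms)
  rr <- pair[!is.na(release_ms) & !is.na(nxt_release_ms)]
  rrl <- .samples(rr$subject_id, rr$press_ms, "RRL",
                  rr$nxt_release_ms - rr$release_ms)
  fp <- pair[!is.na(release_ms)]
  ft <- .samples(fp$subject_id, pmin(fp$press_ms, fp$nxt_press_ms), "FT",
                 fp$nxt_press_ms - fp$release_ms)
  list(ht, ppl, rrl, ft)
}

.correction_blocks <- function(inst) {
  if (nrow(inst) == 0L || !any(inst$key_class == "backspace")) return(list())
  rid <- data.table::rleid(inst$session_id, inst$key_class == "backspace")
  bs <- which(inst$key_class == "backspace")
  runs <- data.table(rid = rid[bs], i = bs)[
    , .(start_i = i[1L], end_i = i[.N]), by = rid]
  first_press <- inst$press_ms[runs$start_i]
  last_release <- inst$release_ms[runs$end_i]
  subj <- inst$subject_id[runs$start_i]
  # neighbours: positions adjacent in the same session (run maximality makes
  # them non-backspace when they exist)
  prev_i <- runs$start_i - 1L
  has_prev <- prev_i >= 1L &
    inst$session_id[pmax(prev_i, 1L)] == inst$session_id[runs$start_i]
  prev_release <- ifelse(has_prev, inst$release_ms[pmax(prev_i, 1L)],
                         NA_real_)
  next_i <- runs$end_i + 1L
  has_next <- next_i <= nrow(inst) &
    inst$session_id[pmin(next_i, nrow(inst))] == inst$session_id[runs$end_i]
  next_press <- ifelse(has_next, inst$press_ms[pmin(next_i, nrow(inst))],
                       NA_real_)
  ok_pre <- !is.na(prev_release)
  pre <- .samples(subj[ok_pre],
                  pmin(prev_release[ok_pre], first_press[ok_pre]),
                  "preCS", first_press[ok_pre] - prev_release[ok_pre])
  ok_cd <- !is.na(last_release)
  cd <- .samples(subj[ok_cd], first_press[ok_cd], "CD",
                 last_release[ok_cd] - first_press[ok_cd])
  ok_post <- !is.na(last_release) & !is.na(next_press)
  post <- .samples(subj[ok_post],
                   pmin(last_release[ok_post], next_press[ok_post]),
                   "postCS", next_press[ok_post] - last_release[ok_post])
  list(pre, cd, post)
}

.punctuation_blocks <- function(inst) {
  pu <- inst[key_class == "punctuation" & !is.na(release_ms) &
               !is.na(nxt_press_ms)]
  list(.samples(pu$subject_id, pmin(pu$release_ms, pu$nxt_press_ms), "APP",
                pu$nxt_press_ms - pu$release_ms))
}

#' Extract timing features (HT, PPL, RRL, FT)
#'
#' Hold time is computed per matched alphanumeric key instance; press-press,
#' release-release and flight latencies are computed for consecutive
#' alphanumeric key instances that are adjacent within a session (no key of
#' any other class in between). Negative flight times (rollover typing) are
#' retained.
#'
#' @param sessions Sessionized events from [segment_sessions()].
#' @param tz Timezone used to date the samples.
#' @return `data.table` with `subject_id`, `date`, `feature`, `value_s`.
#' @export
extract_timing_features <- function(sessions, tz = "UTC") {
  .finish_samples(.timing_blocks(.key_instances(sessions)), tz)
}

#' Extract correction features (preCS, CD, postCS)
#'
#' A maximal run of consecutive backspace key instances within a session is
#' one correction burst. Precorrection slowing is the pause from the release
#' of the last preceding non-backspace key to the first backspace press;
#' correction duration spans first backspace press to last backspace release;
#' postcorrection slowing is the pause from the last backspace release to the
#' press of the first following key. Bursts at session start emit no preCS
#' sample, bursts at session end no postCS sample.
#'
#' @inheritParams extract_timing_features
#' @return `data.table` with `subject_id`, `date`, `feature`, `value_s`.
#' @export
extract_correction_features <- function(sessions, tz = "UTC") {
  .finish_samples(.correction_blocks(.key_instances(sessions)), tz)
}

#' Extract the after-punctuation pause (APP)
#'
#' For every punctuation key instance with a matched release that is followed
#' by another key instance within the same session, APP is the time from the
#' punctuation release to the next press (any key class). A punctuation key
#' that ends a session emits no sample.
#'
#' @inheritParams extract_timing_features
#' @return `data.table` with `subject_id`, `date`, `feature`, `value_s`.
#' @export
extract_punctuation_features <- function(sessions, tz = "UTC") {
  .finish_samples(.punctuation_blocks(.key_instances(sessions)), tz)
}

#' Extract all eight keystroke features from sessionized events
#'
#' Runs the timing, correction and punctuation extractors on a shared
#' press/release-paired key-instance table.
#'
#' @inheritParams extract_timing_features
#' @param cap_s Optional per-sample upper cap in seconds: samples above the
#'   cap are dropped. Default `NULL` (off): the pipeline reports uncapped
#'   latency distributions, the session gap bound already limits pauses.
#' @return `data.table` with `subject_id`, `date`, `feature` (factor over
#'   [kd_features()]), `value_s`, sorted by subject, date, feature.
#' @export
extract_features <- function(sessions, tz = "UTC", cap_s = NULL) {
  inst <- .key_instances(sessions)
  out <- .finish_samples(
    c(.timing_blocks(inst), .correction_blocks(inst),
      .punctuation_blocks(inst)),
    tz, cap_s = cap_s
  )
  out[, feature := factor(feature, levels = kd_features())]
  setorder(out, subject_id, date, feature)
  out[]
}
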