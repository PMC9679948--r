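# Reading, validating, classifying and sessionizing raw keystroke event logs.
#
# Canonical event schema (one row per press or release):
#   subject_id    opaque string
#   timestamp_ms  integer milliseconds since epoch (sub-ms input is truncated)
#   action        "press" or "release"
#   key_class     one of key_classes(), or derived from key_label
#   key_token     optional opaque identifier pairing press/release of the same
#                 key instance; falls back to key_label, then key_class

#' Default punctuation set
#'
#' Key labels classified as punctuation by [classify_key()].
#' @return Character vector.
#' @export
default_punctuation <- function() c(".", ",", ";", ":", "!", "?")

.backspace_tokens <- c("backspace", "bksp", "del", "delete", "\u232b", "<bs>")

#' Classify a raw key label into a key class
#'
#' Deterministic total mapping: single letters and digits are
#' `"alphanumeric"`; deletion-key tokens (`"backspace"`, `"del"`, ...) are
#' `"backspace"`; labels in the configurable punctuation set are
#' `"punctuation"`; everything else (space, return, shift, emoji, ...) is
#' `"other"`.
#'
#' @param key_label Character vector of raw key labels.
#' @param punctuation Punctuation labels (default [default_punctuation()]).
#' @return Character vector of key classes, same length as `key_label`.
#' @examples
#' classify_key(c("a", "7", "backspace", ".", " ", "shift"))
#' @export
classify_key <- function(key_label, punctuation = default_punctuation()) {
  stopifnot(is.character(key_label))
  out <- rep("other", length(key_label))
  out[grepl("^[A-Za-z0-9]$", key_label)] <- "alphanumeric"
  out[tolower(key_label) %in% .backspace_tokens] <- "backspace"
  out[key_label %in% punctuation] <- "punctuation"
  out
}

.required_event_cols <- c("subject_id", "timestamp_ms", "action")

.validate_event_frame <- function(dt, punctuation, quiet = FALSE) {
  for (col in .required_event_cols) {
    if (!col %in% names(dt)) {
      stop("events schema error: missing required column '", col, "'",
           call. = FALSE)
    }
  }
  if (!("key_class" %in% names(dt)) && !("key_label" %in% names(dt))) {
    stop("events schema error: missing required column 'key_class' (or 'key_label')",
         call. = FALSE)
  }
  n_in <- nrow(dt)
  dt[, subject_id := as.character(subject_id)]
  dt[, timestamp_ms := trunc(suppressWarnings(as.numeric(timestamp_ms)))]
  dt[, action := tolower(as.character(action))]

  # key class: computed from the label unless supplied; supplied values are
  # validated and recomputed from the label when invalid
  if ("key_label" %in% names(dt)) {
    dt[, key_label := as.character(key_label)]
    derived <- classify_key(dt$key_label, punctuation)
  } else {
    derived <- rep(NA_character_, nrow(dt))
  }
  if ("key_class" %in% names(dt)) {
    dt[, key_class := as.character(key_class)]
    bad_class <- !(dt$key_class %in% key_classes())
    dt[bad_class, key_class := derived[bad_class]]
  } else {
    dt[, key_class := derived]
  }

  if (!("key_token" %in% names(dt))) dt[, key_token := NA_character_]
  dt[, key_token := as.character(key_token)]
  if ("key_label" %in% names(dt)) {
    dt[is.na(key_token), key_token := key_label[is.na(key_token)]]
  }
  dt[is.na(key_token), key_token := key_class[is.na(key_token)]]

  ok <- !is.na(dt$subject_id) & nzchar(dt$subject_id) &
    !is.na(dt$timestamp_ms) & dt$timestamp_ms >= 0 &
    dt$action %in% c("press", "release") &
    !is.na(dt$key_class) & dt$key_class %in% key_classes()
  n_rejected <- sum(!ok)
  out <- dt[ok, .(subject_id, timestamp_ms, action, key_class, key_token)]
  setorder(out, subject_id, timestamp_ms)
  if (n_rejected > 0L && !quiet) {
    message(n_rejected, " of ", n_in, " event rows rejected as malformed")
  }
  setattr(out, "n_rejected", n_rejected)
  out[]
}

#' Read keystroke event logs
#'
#' Reads a CSV or JSONL event log, validates it against the canonical schema,
#' derives/validates key classes, and returns events sorted by subject and
#' timestamp. Malformed rows (unparseable timestamp, unknown action, missing
#' subject) are rejected and tallied in the `"n_rejected"` attribute.
#'
#' @param path Path to the event file.
#' @param format `"csv"` or `"jsonl"` (one JSON object per line).
#' @param punctuation Punctuation label set for [classify_key()].
#' @param quiet Suppress the rejected-row message.
#' @return A `data.table` with columns `subject_id`, `timestamp_ms`,
#'   `action`, `key_class`, `key_token`, sorted by subject and time, with
#'   attribute `n_rejected`.
#' @seealso [write_events()], [segment_sessions()]
#' @export
read_events <- function(path, format = c("csv", "jsonl"),
                        punctuation = default_punctuation(), quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  if (format == "csv") {
    dt <- data.table::fread(path, integer64 = "double",
                            colClasses = list(character = "subject_id"))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parsed <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    n_bad_lines <- sum(vapply(parsed, is.null, logical(1)))
    dt <- data.table::rbindlist(
      lapply(parsed[!vapply(parsed, is.null, logical(1))], as.data.table),
      fill = TRUE
    )
    if (nrow(dt) == 0L) {
      dt <- data.table(subject_id = character(), timestamp_ms = numeric(),
                       action = character(), key_class = character())
    }
    if (n_bad_lines > 0L && !quiet) {
      message(n_bad_lines, " unparseable JSONL lines skipped")
    }
  }
  if (nrow(dt) == 0L) {
    # header-only file: still enforce schema on the header when present
    if (length(names(dt)) > 0L) {
      for (col in .required_event_cols) {
        if (!col %in% names(dt)) {
          stop("events schema error: missing required column '", col, "'",
               call. = FALSE)
        }
      }
    }
    out <- data.table(subject_id = character(), timestamp_ms = numeric(),
                      action = character(), key_class = character(),
                      key_token = character())
    setattr(out, "n_rejected", 0L)
    return(out[])
  }
  .validate_event_frame(dt, punctuation, quiet = quiet)
}

#' Write keystroke events in the canonical schema
#'
#' @param events Event table as returned by [read_events()].
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  ev <- as.data.table(events)[, .(subject_id, timestamp_ms, action,
                                  key_class, key_token)]
  if (format == "csv") {
    data.table::fwrite(ev, path)
  } else {
    writeLines(vapply(seq_len(nrow(ev)), function(i) {
      jsonlite::toJSON(as.list(ev[i]), auto_unbox = TRUE)
    }, character(1)), path)
  }
  invisible(path)
}

#' Segment per-subject event streams into typing sessions
#'
#' Consecutive events of a subject whose time gap exceeds `max_gap_s` fall in
#' different sessions. Sessions bound the latency computations: no feature
#' ever spans a session break, so pauses of minutes or hours cannot
#' contaminate the latency distributions. The total event count is conserved.
#'
#' @param events Event table (sorted output of [read_events()] or any frame
#'   with the canonical columns).
#' @param max_gap_s Maximum within-session gap in seconds (default 5).
#' @param tz Timezone for the session calendar date (default `"UTC"`).
#' @return The event table with `session_id` and `session_date` columns.
#' @export
segment_sessions <- function(events, max_gap_s = 5.0, tz = "UTC") {
  if (!is.numeric(max_gap_s) || length(max_gap_s) != 1L || max_gap_s < 0) {
    stop("max_gap_s must be a single nonnegative number", call. = FALSE)
  }
  ev <- as.data.table(events)
  if (nrow(ev) == 0L) {
    ev[, `:=`(session_id = character(), session_date = as.Date(character()))]
    return(ev[])
  }
  setorder(ev, subject_id, timestamp_ms)
  ev[, gap_ms := timestamp_ms - shift(timestamp_ms), by = subject_id]
  ev[, new_session := is.na(gap_ms) | gap_ms > max_gap_s * 1000]
  # sessions are numbered across the whole table (each subject opens a new
  # session on its first event), giving an opaque integer session id
  ev[, session_id := cumsum(new_session)]
  ev[, .first_ts := timestamp_ms[1L], by = session_id]
  ev[, session_date := ms_to_date(.first_ts, tz = tz)]
  ev[, c("gap_ms", "new_session", ".first_ts") := NULL]
  ev[]
}
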