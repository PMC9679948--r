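# Brute-force reference implementation of the keystroke features, written as
# plain loops over the raw event list, independent of the package internals.
# Used to cross-check the vectorized extractors on small random sessions.

oracle_features <- function(events, max_gap_s = 5) {
  ev <- as.data.frame(events)
  ev <- ev[order(ev$subject_id, ev$timestamp_ms), ]
  out <- data.frame(feature = character(), value_s = numeric())
  for (subj in unique(ev$subject_id)) {
    se <- ev[ev$subject_id == subj, ]
    # split into sessions on gaps > max_gap_s
    breaks <- c(TRUE, diff(se$timestamp_ms) > max_gap_s * 1000)
    sess_id <- cumsum(breaks)
    for (sid in unique(sess_id)) {
      ss <- se[sess_id == sid, ]
      # positional pairing per token: k-th press matches k-th release (time
      # order); a release preceding its press makes the press unmatched
      press_ms <- numeric(0)
      release_ms <- numeric(0)
      cls <- character(0)
      for (tok in unique(ss$key_token)) {
        st <- ss[ss$key_token == tok, ]
        p <- st$timestamp_ms[st$action == "press"]
        r <- st$timestamp_ms[st$action == "release"]
        for (k in seq_along(p)) {
          press_ms <- c(press_ms, p[k])
          rel <- if (k <= length(r) && r[k] >= p[k]) r[k] else NA_real_
          release_ms <- c(release_ms, rel)
          cls <- c(cls, st$key_class[st$action == "press"][k])
        }
      }
      if (length(press_ms) == 0) next
      o <- order(press_ms)
      press_ms <- press_ms[o]; release_ms <- release_ms[o]; cls <- cls[o]
      n <- length(press_ms)
      add <- function(feature, value_ms) {
        out <<- rbind(out, data.frame(feature = feature,
                                      value_s = value_ms / 1000))
      }
      for (i in seq_len(n)) {
        if (cls[i] == "alphanumeric" && !is.na(release_ms[i])) {
          add("HT", release_ms[i] - press_ms[i])
        }
        if (i < n && cls[i] == "alphanumeric" &&
            cls[i + 1] == "alphanumeric") {
          add("PPL", press_ms[i + 1] - press_ms[i])
          if (!is.na(release_ms[i]) && !is.na(release_ms[i + 1])) {
            add("RRL", release_ms[i + 1] - release_ms[i])
          }
          if (!is.na(release_ms[i])) {
            add("FT", press_ms[i + 1] - release_ms[i])
          }
        }
        if (cls[i] == "punctuation" && !is.na(release_ms[i]) && i < n) {
          add("APP", press_ms[i + 1] - release_ms[i])
        }
      }
      # maximal backspace runs
      i <- 1
      while (i <= n) {
        if (cls[i] == "backspace") {
          j <- i
          while (j < n && cls[j + 1] == "backspace") j <- j + 1
          if (i > 1 && !is.na(release_ms[i - 1])) {
            add("preCS", press_ms[i] - release_ms[i - 1])
          }
          if (!is.na(release_ms[j])) {
            add("CD", release_ms[j] - press_ms[i])
            if (j < n) add("postCS", press_ms[j + 1] - release_ms[j])
          }
          i <- j + 1
        } else {
          i <- i + 1
        }
      }
    }
  }
  out
}

# random small event stream exercising rollover, unmatched presses, orphan
# releases, token reuse and session splits
random_session_events <- function(max_events = 20) {
  n_keys <- sample(1:(max_events %/% 2), 1)
  toks <- c("a", "b", "c", "bs", "dot", "sp")
  classes <- c(a = "alphanumeric", b = "alphanumeric", c = "alphanumeric",
               bs = "backspace", dot = "punctuation", sp = "other")
  t <- 0
  rows <- list()
  for (k in seq_len(n_keys)) {
    tok <- sample(toks, 1)
    gap <- if (runif(1) < 0.1) runif(1, 6, 30) else runif(1, 0.03, 1.2)
    t <- t + gap
    hold <- runif(1, 0.03, 0.25)
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = "X", timestamp_ms = round(t * 1000), action = "press",
      key_class = classes[[tok]], key_token = tok
    )
    if (runif(1) < 0.85) { # 15% unmatched presses
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = "X", timestamp_ms = round((t + hold) * 1000),
        action = "release", key_class = classes[[tok]], key_token = tok
      )
    }
    if (runif(1) < 0.1) { # orphan release
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = "X", timestamp_ms = round((t + hold + 0.01) * 1000),
        action = "release", key_class = classes[[tok]], key_token = tok
      )
    }
    if (runif(1) < 0.15) t <- t - runif(1, 0, hold * 0.8) # rollover
  }
  ev <- do.call(rbind, rows)
  ev[order(ev$timestamp_ms), ]
}

sorted_values_by_feature <- function(df) {
  df <- as.data.frame(df)
  split(df$value_s, df$feature, drop = TRUE) |>
    lapply(sort) |>
    (\(l) l[order(names(l))])()
}
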