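# compact constructor for hand-written event streams: one row per event,
# times in seconds
mk_events <- function(t_s, action, key_label, subject_id = "A",
                      key_token = key_label) {
  data.frame(
    subject_id = subject_id,
    timestamp_ms = round(t_s * 1000),
    action = action,
    key_class = classify_key(key_label),
    key_token = key_token,
    stringsAsFactors = FALSE
  )
}

# a full press+release key at (press, release) seconds
mk_keys <- function(keys, subject_id = "A") {
  # keys: list of list(label, press, release (NA for unmatched), token)
  rows <- lapply(keys, function(k) {
    tok <- if (is.null(k$token)) k$label else k$token
    r <- mk_events(k$press, "press", k$label, subject_id, tok)
    if (!is.null(k$release) && !is.na(k$release)) {
      r <- rbind(r, mk_events(k$release, "release", k$label, subject_id, tok))
    }
    r
  })
  ev <- do.call(rbind, rows)
  ev[order(ev$timestamp_ms), ]
}

feature_values <- function(samples, feat) {
  s <- as.data.frame(samples)
  sort(s$value_s[s$feature == feat])
}

toy_events_path <- function() {
  system.file("extdata", "toy_events.csv", package = "keytype")
}
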