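Package: keytype
Title: Keystroke Dynamics Pipelines for Longitudinal Digital Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Derives keystroke-dynamics timing features (hold time, press-press,
    release-release and flight latencies, correction and punctuation pauses) from
    raw smartphone press/release event logs, aggregates them into daily records and
    visit-window composite scores (a fine motor score cluster and a cognition score
    cluster), and quantifies their longitudinal association with clinical outcomes
    (Nine-Hole Peg Test, Symbol Digit Modalities Test) through random-intercept and
    hybrid between-/within-subject linear mixed models. Includes a synthetic cohort
    generator with known ground truth for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
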