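Package: fuzzscore
Title: Fuzzy String Matching Metrics for Scoring Listener Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated scoring of listener transcripts in speech
    intelligibility research using fuzzy (approximate) string matching.
    Implements the Levenshtein edit distance, the Jaro distance with its
    matching-window rule, and the token sort ratio built on a recursive
    longest-matching-block sequence ratio, together with the text
    preprocessing these metrics assume (punctuation removal, whitespace
    collapsing, case folding), a CSV batch scorer that appends a
    'TSR_score' column to target/response tables, a seeded simulator of
    listener responses with a known ground-truth report fraction, and an
    evaluation harness correlating each metric with a reference score.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    readr,
    stats,
    stringi,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
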