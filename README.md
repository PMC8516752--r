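# fuzzscore

Automated scoring of listener transcripts in speech intelligibility
research by fuzzy (approximate) string matching.

Transcription tasks ("type out what you hear") are usually scored by humans
as the percentage of target words correctly reported — slow, and dependent
on which scoring protocol the lab uses. `fuzzscore` replaces that judgment
with deterministic string metrics computed on the typed response and the
target sentence, so a near-miss like *wayer* for *water* (one key to the
right on a QWERTY keyboard) earns nearly full credit instead of none.

## The metrics

For a normalized target of length *A* and response of length *B*:

* **Levenshtein distance** — minimum number of single-character insertions,
  deletions, and substitutions converting one string into the other
  (spaces count as characters). 0 means a perfect match; unbounded above.
* **Jaro distance** — `1 − (1/3)(s/A + s/B + (s − n)/s)`, where *s* counts
  matching characters whose positions differ by at most
  `floor(max(A, B)/2) − 1` and *n* counts transpositions; 0 for identical
  strings, 1 for strings with no matching characters.
* **Token sort ratio (TSR)** — sort each string's words alphabetically,
  then score `2M/T × 100`, where *M* is the summed length of the shared
  substrings found by recursive longest-common-substring decomposition and
  *T* the summed length of both strings. Word-order invariant, 0–100.

Around them: the preprocessing the metrics assume (`normalize_text()`), an
automated percent-words-correct reference (`word_overlap_pwc()`), a CSV
batch scorer (`score_file()`: columns `target`/`response` in, `TSR_score`
appended out), a seeded simulator of typed listener responses with known
ground truth (`simulate_corpus()`), an evaluation harness
(`evaluate_metrics()`), and a command-line wrapper
(`inst/cli/fuzzscore`).

## Worked example

```r
library(fuzzscore)
score_pair("The big blue house is for sale", "the hous is for sale")
#>                           target             response
#> 1 The big blue house is for sale the hous is for sale
#>                      target_norm        response_norm TSR_score LS_score
#> 1 the big blue house is for sale the hous is for sale        80       10
#>   Jaro_score PWC_auto
#> 1  0.2444444 57.14286
```

The response reports five of the seven target words, one misspelled: TSR
credits the orthographic overlap (80/100), 10 character edits separate the
normalized strings, the Jaro distance is 0.244 (0 = identical), and the
exact-word-overlap reference scores 4/7 of the target words, 57.1%.

Validating the metrics against the simulator's ground truth:

```r
corpus <- simulate_corpus(300, seed = 21)
scored <- cbind(corpus, score_pair(corpus$target, corpus$response)[
  c("TSR_score", "LS_score", "Jaro_score", "PWC_auto")])
evaluate_metrics(scored)
#>       metric          r   n expected_sign sign_ok
#> 1   LS_score -0.7086738 300             -    TRUE
#> 2 Jaro_score -0.8031503 300             -    TRUE
#> 3  TSR_score  0.9571182 300             +    TRUE
#> 4   PWC_auto  0.9412016 300             +    TRUE
```

Each row is one metric's Pearson correlation with the true fraction of
target words the simulated listener reported: the distances anti-correlate,
the similarity scores correlate, and TSR tracks the ground truth most
closely — the pattern that motivates using TSR for transcript scoring.

See `vignettes/transcript-scoring.Rmd` for the model details, simulator
design, and known limitations.

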