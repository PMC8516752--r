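---
title: "Scoring listener transcripts with fuzzy string matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring listener transcripts with fuzzy string matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzscore)
```

## The scoring problem

Speech intelligibility experiments routinely ask listeners to *type out what
they hear*, and express the intelligibility of a stimulus as the percentage
of target words correctly reported (PWC). Scoring thousands of typed
responses by hand is slow, and human protocols disagree about misspellings,
grammatical variants, and word order. Fuzzy (approximate) string matching
replaces the human judgment with a deterministic function of the two
character strings: a typed response that is *almost* the target ("wayer" for
"water" — one key to the right) should earn almost full credit.

`fuzzscore` implements three such metrics, the preprocessing they assume, a
CSV batch scorer, a synthetic listener-response simulator, and a small
evaluation harness.

## Preprocessing

All metrics operate on a canonical form produced by `normalize_text()`:
punctuation and symbols removed (Unicode categories P and S, so the rule is
language-independent), whitespace collapsed to single spaces, characters
lowercased with full Unicode case folding. Two choices are deliberately
configurable because no single convention fits every orthography:

* dash/connector punctuation and slashes become a *space* rather than being
  deleted, so "blue-green" keeps its two word tokens;
* apostrophes are deleted *in place* ("it's" → "its"), mirroring common
  transcription-scoring practice.

Normalization is idempotent, maps all-punctuation input to the empty
string, and tokenization simply splits on spaces, so joining tokens
reproduces the normalized text exactly. Numerals are kept as token content.
Whether punctuation stripping should interact with tokenization differently
(e.g., for clitic-rich languages) was an open design point; the rules above
are this package's own convention and are switchable via
`remove_punctuation`, `lowercase`, `dash_to_space`, and `drop_apostrophes`.

## The metrics

**Levenshtein distance** (`levenshtein()`): minimum number of unit-cost
insertions, deletions, and substitutions. Spaces count as ordinary
characters, which is what makes the sentence-versus-single-word example
("the big blue house is for sale" vs. "sail") cost 27 edits. The scale is
unbounded above, so it *anti*-correlates with intelligibility.

**Jaro distance** (`jaro_distance()`): designed for short human-typed
fields. With target length $A$, response length $B$, $s$ matching
characters and $n$ transpositions,

$$J = 1 - \frac{1}{3}\left(\frac{s}{A} + \frac{s}{B} + \frac{s-n}{s}\right).$$

Two identical characters only *match* when their positions differ by at
most $\lfloor \max(A,B)/2\rfloor - 1$ (floored, clamped at zero —
`match_window()`). Matching is greedy left-to-right; $n$ is half the number
of matched positions whose order differs, rounded down (the standard
convention; the worked examples all have $n = 0$ and cannot disambiguate,
so the choice is pinned by an exhaustive-matching oracle in the tests).
Degenerate cases follow the "no matching characters yield 1" logic: one
empty string gives 1, two empty strings give 0.

**Token sort ratio** (`token_sort_ratio()`): the words of each string are
sorted alphabetically (by code point), joined with single spaces, and the
two sorted strings are compared by the matching-block sequence ratio
$2M/T \times 100$, where $M$ sums the lengths of the non-overlapping shared
substrings found by recursive longest-common-substring decomposition
(`matching_blocks()`) and $T$ is the summed length of both strings. Sorting
makes the score word-order invariant (`"mary saw john"` vs.
`"john saw mary"` scores 100); empty responses score 0. No junk/popularity
heuristics are used in the block decomposition, so results do not depend on
input size; ties between equally long blocks go to the smallest start
position in the first string, then the second.

One printed example is computed *excluding* whitespace from $M$ and $T$;
reference implementations of the sequence ratio count the joining spaces.
Both conventions give 80 on that example, and both are available via
`count_spaces` (default `TRUE`, the reference behavior). Scores are kept in
full precision; `round_score = TRUE` rounds half-up to integers, matching
the printed values.

```{r}
token_sort_ratio("water", "wayer")
jaro_distance("water", "wayer")
levenshtein("the big blue house is for sale", "sail")
```

## Batch scoring

`score_file()` reproduces the published I/O contract: a UTF-8 CSV with
columns `target` and `response` in, the same table with `TSR_score`
appended out (plus `LS_score`, `Jaro_score`, `PWC_auto` on request). Input
columns, cell bytes, and row order are preserved; missing and empty
response cells both score as empty strings (TSR 0) and are counted in the
run summary; missing required columns, undecodable input, and ragged rows
are hard errors — no silent repair. A thin command-line wrapper
(`inst/cli/fuzzscore`, subcommands `pair`, `score`, `simulate`,
`evaluate`) exposes the same functions from a shell.

## What the simulator emulates — and what it does not

`simulate_corpus()` generates target sentences (5–20 words by default,
drawn from a packaged 200-word neutral lexicon) and corrupts each one with
the error processes typed transcripts actually exhibit:

* **omission** — each word is reported with probability `report_prob`; the
  default draws each record's probability uniformly from $[0,1]$ so a
  corpus spans the whole intelligibility scale;
* **adjacent-key typos** — each character is substituted by a QWERTY
  neighbor with probability `typo_rate` (default 0.05, a deliberately
  noticeable rate: roughly one typo per four five-letter words); the
  adjacency map is configurable so other keyboard layouts or orthographies
  can be simulated;
* **word-order scrambling** with probability `shuffle_prob` (default 0.1);
* **intrusions** — a Poisson number (mean `intrusion_rate`, default 0.5)
  of lexicon words *not* in the target, inserted at random positions, so
  the ground-truth report fraction stays well defined.

The ground truth `true_report_fraction` counts kept words before typos —
a typo corrupts spelling, not the report. The random stream is split per
record from the master seed, so any single record is reproducible on its
own. Defaults were fixed once, on the reasoning above, as what a listening
experiment at moderate noise plausibly produces; they are free parameters
of the simulation, not estimates fitted to any real dataset.

What passing tests on this corpus shows is therefore *methodological*: the
metrics rank synthetic transcripts the way they should rank real ones under
these error processes. Real listener data add phenomena the simulator does
not model — phonological confusions, guesses correlated with the target,
morphological variants, content-word scoring protocols — so correlation
magnitudes on real data cannot be inferred from the synthetic ones, only
the directions and relative behavior.

## The evaluation harness

`word_overlap_pwc()` is the automated, exact-match stand-in for a human PWC
reference: the *multiset* intersection of target and response tokens over
the target word count, times 100. Multiset (not set) counting means a
repeated target word must be reported each time to earn credit. All tokens
count; restricting to content words would require language-specific
knowledge, which the package deliberately avoids. The human allowance for
misspellings is a judgment, not a computation, and is out of scope.

`evaluate_metrics()` correlates each metric column with a reference column
(Pearson's r, pooled over trials) and checks the expected signs: negative
for the two distances, positive for the two similarity scores. Constant
inputs raise an explicit undefined-correlation error rather than silently
producing `NA`. On the default seeded corpus ($n = 1000$) the sign pattern
is (−, −, +, +) and the TSR–reference correlation exceeds 0.8; with all
error processes disabled, `PWC_auto` is an exact deterministic function of
the report fraction and correlates perfectly with it. These are property
gates on synthetic data — the correlations published for human-scored
datasets require those datasets and are intentionally not reproduced here.

```{r}
corpus <- simulate_corpus(300, seed = 21)
scored <- cbind(corpus, score_pair(corpus$target, corpus$response)[
  c("TSR_score", "LS_score", "Jaro_score", "PWC_auto")])
evaluate_metrics(scored)
```

## Numerical and testing choices

* Metric kernels run on integer code-point sequences (C++ via Rcpp), so
  every routine is Unicode-correct and fast enough to score tens of
  thousands of rows in seconds.
* Ratios are computed in full double precision; tests compare unrounded
  values at tight tolerances and rounded ones exactly.
* Test problem sizes — 1,000 random pairs against a memoized recursive
  edit-distance oracle (length ≤ 12), 500 pairs against an exhaustive
  Jaro matching oracle (length ≤ 8), 500 pairs against an exhaustive
  longest-common-substring search (length ≤ 15), and a 1,000-record
  simulated corpus — keep the whole suite under a minute while covering
  the collision-rich small-alphabet cases where the algorithms can break.

## Known limitations

* All metrics are orthographic, not phonological: "eye" for "I" scores
  poorly despite the perfect homophony. A pronunciation-dictionary layer
  would be language-specific and is deliberately absent.
* TSR rewards accidental character overlap, so it tends to overestimate
  accuracy at the low end of the scale.
* The Levenshtein scale is unbounded; comparisons across targets of very
  different lengths need care.
* The simulator's error rates are conventions, not estimates; use your own
  `error_model()` when a specific population or keyboard is of interest.
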