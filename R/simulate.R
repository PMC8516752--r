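#' QWERTY keyboard adjacency map
#'
#' Adjacency of letter keys on a standard QWERTY layout: left and right
#' neighbors in the same row plus the vertically adjacent keys in the rows
#' above and below (the staggered layout puts two keys below most letters,
#' e.g. `t` neighbors `r`, `y`, `f`, and `g`). Used as the default typo
#' model in [corrupt_response()]: a typo substitutes a character by one of
#' its neighbors, the way "wayer" arises from "water" by hitting the key
#' next to T. Any named list of character vectors can be supplied instead,
#' so non-Latin orthographies can be simulated.
#'
#' @return A named list mapping each lowercase letter to its neighbors.
#' @examples
#' qwerty_adjacency()[["t"]]
#' @export
qwerty_adjacency <- function() {
  rows <- c("qwertyuiop", "asdfghjkl", "zxcvbnm")
  chars <- lapply(rows, function(r) strsplit(r, "")[[1]])
  map <- list()
  for (ri in seq_along(chars)) {
    row <- chars[[ri]]
    for (ci in seq_along(row)) {
      nb <- character(0)
      if (ci > 1) nb <- c(nb, row[ci - 1])
      if (ci < length(row)) nb <- c(nb, row[ci + 1])
      # row below is shifted half a key right: keys ci-1 and ci sit under ci
      if (ri < length(chars)) {
        below <- chars[[ri + 1]]
        for (k in c(ci - 1, ci)) if (k >= 1 && k <= length(below))
          nb <- c(nb, below[k])
      }
      # row above: keys ci and ci+1 sit over ci
      if (ri > 1) {
        above <- chars[[ri - 1]]
        for (k in c(ci, ci + 1)) if (k >= 1 && k <= length(above))
          nb <- c(nb, above[k])
      }
      map[[row[ci]]] <- unique(nb)
    }
  }
  map
}

#' Default simulation lexicon
#'
#' A neutral list of 200 common English words used to build synthetic target
#' sentences and intrusion words. Packaged so simulations need no external
#' resources; any non-empty character vector can be used instead.
#'
#' @return Character vector of 200 lowercase words.
#' @export
default_lexicon <- function() {
  c("about", "after", "again", "air", "all", "along", "also", "animal",
    "another", "answer", "any", "around", "ask", "away", "back", "because",
    "been", "before", "began", "begin", "below", "between", "big", "blue",
    "boat", "book", "both", "boy", "bring", "build", "call", "came", "car",
    "carry", "change", "children", "city", "close", "cold", "come", "could",
    "country", "cut", "day", "deep", "different", "does", "dog", "down",
    "draw", "each", "earth", "eat", "end", "even", "every", "example",
    "eye", "face", "family", "far", "farm", "father", "feet", "few", "find",
    "fire", "first", "fish", "follow", "food", "form", "found", "four",
    "from", "girl", "give", "good", "great", "green", "group", "grow",
    "hand", "hard", "head", "hear", "help", "here", "high", "home", "horse",
    "house", "idea", "important", "into", "just", "keep", "kind", "know",
    "land", "large", "last", "later", "learn", "leave", "left", "letter",
    "life", "light", "like", "line", "list", "little", "live", "long",
    "look", "made", "make", "man", "many", "mean", "men", "might", "mile",
    "miss", "more", "most", "mother", "mountain", "move", "much", "must",
    "name", "near", "need", "never", "new", "next", "night", "number",
    "off", "often", "old", "once", "only", "open", "other", "our", "over",
    "own", "page", "paper", "part", "people", "picture", "place", "plant",
    "play", "point", "put", "question", "quick", "read", "right", "river",
    "road", "run", "said", "same", "saw", "say", "school", "sea", "second",
    "see", "seem", "sentence", "set", "she", "should", "show", "side",
    "small", "something", "sound", "spell", "start", "state", "still",
    "stop", "story", "study", "such", "take", "talk", "tell", "than",
    "thing", "think", "this", "thought", "three", "through", "time",
    "together", "tree", "try", "turn", "under", "until", "walk", "want",
    "water", "way", "well", "went", "where", "which", "while", "white",
    "why", "word", "work", "world", "would", "write", "year", "young")
}

#' Listener-response error model
#'
#' Parameters of the generative model behind [corrupt_response()] and
#' [simulate_corpus()], emulating how typed listener transcripts deviate
#' from the target sentence: words are omitted under noise, typed characters
#' are substituted by adjacent keys, word order is sometimes scrambled, and
#' extraneous (guessed) words intrude.
#'
#' @param report_prob Probability that a target word is reported. Either a
#'   single value in \[0, 1\] or a length-2 range from which each record
#'   draws its own probability uniformly (the default, `c(0, 1)`, spreads
#'   records over the whole intelligibility scale).
#' @param typo_rate Per-character probability of an adjacent-key
#'   substitution in \[0, 1\].
#' @param shuffle_prob Probability that the reported words are permuted.
#' @param intrusion_rate Expected number of extraneous words per response
#'   (Poisson).
#' @param keyboard_map Named list mapping characters to candidate
#'   substitution characters; see [qwerty_adjacency()].
#' @return An object of class `error_model` (a validated list).
#' @examples
#' error_model(report_prob = 0.7, typo_rate = 0.02)
#' @export
error_model <- function(report_prob = c(0, 1), typo_rate = 0.05,
                        shuffle_prob = 0.1, intrusion_rate = 0.5,
                        keyboard_map = qwerty_adjacency()) {
  stopifnot(length(report_prob) %in% 1:2,
            all(report_prob >= 0 & report_prob <= 1),
            length(typo_rate) == 1, typo_rate >= 0, typo_rate <= 1,
            length(shuffle_prob) == 1, shuffle_prob >= 0, shuffle_prob <= 1,
            length(intrusion_rate) == 1, intrusion_rate >= 0,
            is.list(keyboard_map))
  if (length(report_prob) == 2 && report_prob[1] > report_prob[2])
    stop("report_prob range must be non-decreasing")
  structure(list(report_prob = report_prob, typo_rate = typo_rate,
                 shuffle_prob = shuffle_prob,
                 intrusion_rate = intrusion_rate,
                 keyboard_map = keyboard_map),
            class = "error_model")
}

#' Generate synthetic target sentences
#'
#' Draws `n` sentences of uniformly random length within `length_range`,
#' with words sampled (with replacement) from the lexicon. Deterministic
#' given the seed.
#'
#' @param n Number of sentences (>= 1).
#' @param length_range Integer vector `c(min, max)` word counts; the default
#'   5–20 matches typical sentence materials in intelligibility studies.
#' @param lexicon Non-empty character vector of words.
#' @param seed Integer seed.
#' @return Character vector of `n` sentences.
#' @examples
#' generate_targets(3, c(5, 5), seed = 42)
#' @export
generate_targets <- function(n, length_range = c(5, 20),
                             lexicon = default_lexicon(), seed = 1L) {
  stopifnot(n >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  if (length(lexicon) == 0)
    stop("lexicon must be non-empty")
  set.seed(seed)
  lens <- sample.int(length_range[2] - length_range[1] + 1L, n,
                     replace = TRUE) + length_range[1] - 1L
  vapply(lens, function(k)
    paste(sample(lexicon, k, replace = TRUE), collapse = " "),
    character(1))
}

#' Corrupt a target sentence into a simulated listener response
#'
#' Applies the error model to one target: each word is kept independently
#' with the report probability; kept words receive per-character
#' adjacent-key substitutions; with the shuffle probability the kept words
#' are permuted; intrusion words drawn from the lexicon (excluding the
#' target's own words) are inserted at random positions. The ground-truth
#' report fraction is the number of kept words over the number of target
#' words, counted *before* typos — typos corrupt spelling, not the report.
#'
#' Uses the current R random stream; seed it (or use [simulate_corpus()],
#' which seeds per record) for reproducibility.
#'
#' @param target Non-empty raw sentence string.
#' @param model An [error_model()].
#' @param lexicon Word pool for intrusions.
#' @return A one-row data frame with columns `target`, `response`,
#'   `true_report_fraction`, `n_typos`.
#' @examples
#' set.seed(7)
#' corrupt_response("the big blue house is for sale",
#'                  error_model(report_prob = 0.7))
#' @export
corrupt_response <- function(target, model = error_model(),
                             lexicon = default_lexicon()) {
  stopifnot(inherits(model, "error_model"), length(target) == 1,
            nzchar(target))
  words <- tokenize(normalize_text(target))[[1]]
  n_words <- length(words)
  p <- model$report_prob
  if (length(p) == 2) p <- runif(1, p[1], p[2])
  kept_mask <- rbinom(n_words, 1L, p) == 1L
  kept <- words[kept_mask]
  fraction <- sum(kept_mask) / n_words
  n_typos <- 0L
  if (length(kept) > 0 && model$typo_rate > 0) {
    kept <- vapply(kept, function(w) {
      ch <- strsplit(w, "")[[1]]
      for (i in seq_along(ch)) {
        nb <- model$keyboard_map[[ch[i]]]
        if (!is.null(nb) && runif(1) < model$typo_rate) {
          ch[i] <- sample(nb, 1)
          n_typos <<- n_typos + 1L
        }
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  if (length(kept) > 1 && runif(1) < model$shuffle_prob)
    kept <- sample(kept)
  n_intr <- rpois(1, model$intrusion_rate)
  if (n_intr > 0) {
    pool <- setdiff(lexicon, words)
    if (length(pool) > 0) {
      intr <- sample(pool, min(n_intr, length(pool)), replace = FALSE)
      for (w in intr) {
        pos <- sample.int(length(kept) + 1L, 1L) - 1L
        kept <- append(kept, w, after = pos)
      }
    }
  }
  data.frame(target = target, response = paste(kept, collapse = " "),
             true_report_fraction = fraction, n_typos = n_typos,
             stringsAsFactors = FALSE)
}

#' Simulate a scored corpus of target/response pairs
#'
#' Generates `n` synthetic trials: target sentences from the lexicon and
#' listener responses corrupted under the error model, each carrying its
#' ground-truth report fraction. The random stream is split per record from
#' the master seed, so any record is independently reproducible and
#' identical seeds give identical corpora.
#'
#' @param n Number of trials.
#' @param model An [error_model()].
#' @param length_range,lexicon Passed to [generate_targets()].
#' @param seed Master integer seed.
#' @return A data frame with columns `target`, `response`,
#'   `true_report_fraction`, `n_typos`.
#' @examples
#' head(simulate_corpus(5, seed = 42))
#' @export
simulate_corpus <- function(n = 1000, model = error_model(),
                            length_range = c(5, 20),
                            lexicon = default_lexicon(), seed = 1L) {
  targets <- generate_targets(n, length_range, lexicon, seed = seed)
  set.seed(seed + 1L)
  record_seeds <- sample.int(.Machine$integer.max - 1L, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(record_seeds[i])
    rows[[i]] <- corrupt_response(targets[i], model, lexicon)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
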