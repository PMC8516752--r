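#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions, and
#' substitutions required to convert one string into the other, at unit cost.
#' Spaces count as ordinary characters, so for sentence strings the distance
#' includes the edits on the separators. A value of 0 indicates a perfect
#' match; the scale is unbounded above (an empty response scores the length
#' of the target). For transcript scoring a *negative* association with
#' intelligibility is therefore expected.
#'
#' Inputs are compared as given; apply [normalize_text()] first when scoring
#' raw transcripts.
#'
#' @param a,b Character vectors, recycled to a common length.
#' @return Integer vector of edit distances.
#' @examples
#' levenshtein("water", "wayer")                         # 1
#' levenshtein("the big blue house is for sale", "sail") # 27
#' @export
levenshtein <- function(a, b) {
  p <- .pair_recycle(a, b)
  mapply(function(x, y) .lev_cpp(.codepoints(x), .codepoints(y)),
         p$a, p$b, USE.NAMES = FALSE)
}

#' Jaro matching window
#'
#' Maximum allowed difference in character position (counting from the left
#' in each string) for two identical characters to count as a Jaro match:
#' half the length of the longest input string, minus one, floored and
#' clamped at zero.
#'
#' @param len_a,len_b Non-negative integer string lengths, recycled.
#' @return Integer vector of window sizes.
#' @examples
#' match_window(30, 4) # 14
#' match_window(1, 1)  # 0
#' @export
match_window <- function(len_a, len_b) {
  pmax(0L, pmax(as.integer(len_a), as.integer(len_b)) %/% 2L - 1L)
}

#' Jaro distance components
#'
#' Decomposes one string pair into the quantities the Jaro distance is built
#' from: the two string lengths `A` and `B`, the number of matching
#' characters `s` under the window rule (see [match_window()]), and the
#' transposition count `n`. Matching is greedy: scanning the second string
#' left to right, each character matches the leftmost unmatched identical
#' character of the first string within the window. `n` is half the number
#' of matched positions whose order differs between the two matched
#' sequences, rounded down.
#'
#' @param a,b Single strings (normalized; spaces are ordinary characters).
#' @return A list with elements `A`, `B`, `s`, `n`, `window`.
#' @examples
#' jaro_components("water", "wayer") # A = 5, B = 5, s = 4, n = 0
#' @export
jaro_components <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  ca <- .codepoints(a); cb <- .codepoints(b)
  v <- .jaro_cpp(ca, cb)
  list(A = length(ca), B = length(cb), s = v[[1]], n = v[[2]],
       window = v[[3]])
}

#' Jaro distance
#'
#' A heuristic string distance developed for linking short human-typed text
#' fields: from the components of [jaro_components()] it evaluates
#' \deqn{1 - \frac{1}{3}\left(\frac{s}{A} + \frac{s}{B} +
#'   \frac{s-n}{s}\right)}{1 - (1/3) (s/A + s/B + (s - n)/s)}
#' Identical non-empty strings yield 0; strings with no matching characters
#' yield 1. When exactly one string is empty the distance is 1; when both
#' are empty it is 0 (no mismatching evidence).
#'
#' @param a,b Character vectors, recycled to a common length.
#' @return Numeric vector of distances in \[0, 1\].
#' @examples
#' jaro_distance("water", "wayer")                         # 0.1333...
#' jaro_distance("the big blue house is for sale", "sail") # 0.4777...
#' @export
jaro_distance <- function(a, b) {
  p <- .pair_recycle(a, b)
  mapply(function(x, y) {
    cc <- jaro_components(x, y)
    if (cc$A == 0L && cc$B == 0L) return(0)
    if (cc$s == 0L) return(1)
    1 - (cc$s / cc$A + cc$s / cc$B + (cc$s - cc$n) / cc$s) / 3
  }, p$a, p$b, USE.NAMES = FALSE)
}

#' Matching-block decomposition of a string pair
#'
#' Recursive longest-matching-block decomposition: find the longest common
#' contiguous substring (ties broken by smallest start in `a`, then in `b`),
#' then recurse on the unmatched prefixes and suffixes. The returned blocks
#' are non-overlapping and strictly increasing in both coordinates, and
#' their summed length is the `M` of [sequence_ratio()]. No junk or
#' popularity heuristics are applied, so the decomposition does not depend
#' on input size.
#'
#' @param a,b Single strings.
#' @return A data frame with one row per block and integer columns
#'   `a_start`, `b_start` (1-based start positions) and `length`. Strings
#'   with no common characters give zero rows.
#' @examples
#' matching_blocks("big blue for house is sale the", "for hous is sale the")
#' @export
matching_blocks <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  m <- .blocks_cpp(.codepoints(a), .codepoints(b))
  data.frame(a_start = m[, 1] + 1L, b_start = m[, 2] + 1L, length = m[, 3])
}

#' Matching-block sequence ratio
#'
#' `2 * M / T`, where `M` is the summed length of the matching blocks of the
#' pair and `T` the summed length of both strings. Equals 1 for identical
#' strings and 0 when no substring is shared. With `count_spaces = FALSE`,
#' spaces are excluded from both `M` and `T` (the arithmetic used in the
#' worked sentence example); the default counts them.
#'
#' @param a,b Single strings, not both empty.
#' @param count_spaces Count space characters toward `M` and `T` (default
#'   `TRUE`).
#' @return A single number in \[0, 1\]. Both-empty input returns 1 (trivially
#'   identical strings).
#' @examples
#' sequence_ratio("water", "wayer") # 0.8 (M = 4, T = 10)
#' @export
sequence_ratio <- function(a, b, count_spaces = TRUE) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  rc <- ratio_components(a, b, count_spaces = count_spaces)
  if (rc$T == 0L) return(1)
  2 * rc$M / rc$T
}

#' @rdname sequence_ratio
#' @return For `ratio_components()`, a list with integer elements `M` and
#'   `T`.
#' @export
ratio_components <- function(a, b, count_spaces = TRUE) {
  ca <- .codepoints(a); cb <- .codepoints(b)
  blocks <- .blocks_cpp(ca, cb)
  if (count_spaces) {
    M <- sum(blocks[, 3])
    Tt <- length(ca) + length(cb)
  } else {
    sp <- utf8ToInt(" ")
    M <- 0L
    if (nrow(blocks) > 0)
      for (r in seq_len(nrow(blocks))) {
        seg <- ca[seq.int(blocks[r, 1] + 1L, length.out = blocks[r, 3])]
        M <- M + sum(seg != sp)
      }
    Tt <- sum(ca != sp) + sum(cb != sp)
  }
  list(M = as.integer(M), T = as.integer(Tt))
}

#' Token sort ratio (TSR)
#'
#' The transcript-accuracy score this package is built around: each string's
#' tokens (words) are sorted alphabetically, the sorted tokens are joined
#' with single spaces, and the matching-block sequence ratio of the two
#' sorted strings is scaled to 0–100. Because of the sorting step the score
#' is invariant under word-order differences ("john saw mary" against
#' "mary saw john" scores 100). Identical strings score 100; strings without
#' matching characters score 0, as does any empty response.
#'
#' @param target,response Character vectors, recycled to a common length. By
#'   default raw strings are accepted and passed through [normalize_text()];
#'   set `normalize = FALSE` when inputs are already normalized.
#' @param count_spaces Whether the single joining spaces between sorted
#'   tokens count toward `M` and `T` (default `TRUE`, the reference-tool
#'   behavior); `FALSE` reproduces the whitespace-excluded arithmetic. Both
#'   modes yield the same score on the package's worked examples.
#' @param round_score Round the score half-up to an integer (default
#'   `FALSE`: full precision).
#' @param normalize Apply [normalize_text()] to both inputs first (default
#'   `TRUE`).
#' @return Numeric vector of scores in \[0, 100\].
#' @examples
#' token_sort_ratio("water", "wayer")                                     # 80
#' token_sort_ratio("The big blue house is for sale",
#'                  "the hous is for sale")                               # 80
#' token_sort_ratio("Mary saw John", "John saw Mary")                     # 100
#' @export
token_sort_ratio <- function(target, response, count_spaces = TRUE,
                             round_score = FALSE, normalize = TRUE) {
  p <- .pair_recycle(target, response)
  a <- p$a; b <- p$b
  if (normalize) {
    a <- normalize_text(a)
    b <- normalize_text(b)
  }
  a <- sort_tokens(a)
  b <- sort_tokens(b)
  out <- mapply(function(x, y) {
    if (!nzchar(x) || !nzchar(y)) return(0)
    100 * sequence_ratio(x, y, count_spaces = count_spaces)
  }, a, b, USE.NAMES = FALSE)
  if (round_score) out <- floor(out + 0.5)
  out
}

# Recycle two vectors to a common length, erroring on incompatible lengths.
.pair_recycle <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- max(length(a), length(b))
  if (n > 0 && (length(a) == 0L || length(b) == 0L))
    stop("cannot recycle a zero-length argument against a non-empty one")
  if (n %% max(1L, length(a)) != 0L || n %% max(1L, length(b)) != 0L)
    stop("argument lengths are not compatible for recycling")
  list(a = rep_len(a, n), b = rep_len(b, n))
}
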