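#' Normalize orthographic strings for fuzzy matching
#'
#' Applies the preprocessing that all transcript-accuracy metrics in this
#' package assume: punctuation and symbol removal, whitespace collapsing, and
#' lowercasing. Dash- and connector-type punctuation (hyphens, slashes,
#' underscores) is replaced by a space so that compounds like `"blue-green"`
#' keep their word boundary, while apostrophes are deleted in place
#' (`"it's"` becomes `"its"`), mirroring common transcription-scoring
#' practice. All other punctuation and symbol characters (Unicode categories
#' P and S) are deleted. Runs of whitespace collapse to a single space and
#' leading/trailing whitespace is trimmed, so normalization is idempotent.
#'
#' Case folding and category matching use full Unicode semantics (via
#' \pkg{stringi}), so any UTF-8 orthography is supported; numerals and other
#' non-letter word characters are retained as token content.
#'
#' @param x Character vector of raw strings. `NA` is treated as the empty
#'   string.
#' @param remove_punctuation Remove punctuation/symbol characters (default
#'   `TRUE`).
#' @param lowercase Apply Unicode case folding (default `TRUE`).
#' @param dash_to_space Replace dash/connector punctuation and slashes by a
#'   space instead of deleting them (default `TRUE`).
#' @param drop_apostrophes Delete apostrophes in place rather than treating
#'   them as ordinary punctuation (default `TRUE`; only meaningful when
#'   `remove_punctuation` is `TRUE`).
#'
#' @return For `normalize_text()`, a character vector the same length as `x`:
#'   lowercase, single-space separated, no leading/trailing whitespace. An
#'   all-punctuation or all-whitespace input yields `""`. For `tokenize()`, a
#'   list of character vectors of non-empty tokens (joining a tokens vector
#'   with single spaces reproduces the normalized string exactly). For
#'   `sort_tokens()`, a character vector in which the tokens of each element
#'   have been sorted by code point, duplicates preserved.
#'
#' @examples
#' normalize_text("  Water,   please!! ")   # "water please"
#' tokenize("The big blue house is for sale")[[1]]
#' sort_tokens("the big blue house is for sale")
#' @export
normalize_text <- function(x, remove_punctuation = TRUE, lowercase = TRUE,
                           dash_to_space = TRUE, drop_apostrophes = TRUE) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- enc2utf8(x)
  if (remove_punctuation) {
    if (drop_apostrophes)
      x <- stringi::stri_replace_all_regex(x, "['’‘ʼ]", "")
    if (dash_to_space)
      x <- stringi::stri_replace_all_regex(x, "[\\p{Pd}\\p{Pc}/\\\\]", " ")
    x <- stringi::stri_replace_all_regex(x, "[\\p{P}\\p{S}]", "")
  }
  if (lowercase)
    x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

#' @rdname normalize_text
#' @export
tokenize <- function(x) {
  x <- as.character(x)
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    stringi::stri_split_fixed(s, " ")[[1]]
  })
}

#' @rdname normalize_text
#' @export
sort_tokens <- function(x) {
  toks <- tokenize(x)
  vapply(toks, function(t) {
    if (length(t) == 0) return("")
    # radix sort on UTF-8 bytes == code-point order; stable for duplicates
    paste(sort(t, method = "radix"), collapse = " ")
  }, character(1))
}
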