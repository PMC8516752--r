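#' Automated percentage-words-correct (exact word overlap)
#'
#' The automated, exact-match variant of the traditional percentage-words-
#' correct reference score: the number of words shared between target and
#' response divided by the number of words in the target, times 100. The
#' intersection is over *multisets*, so a word repeated in the target must be
#' reported as often to earn full credit, and is order-free. Unlike
#' human-protocol PWC no allowance is made for misspellings, and all tokens
#' count (no content-word filtering).
#'
#' @param target,response Character vectors, recycled to a common length.
#'   Raw strings are normalized first unless `normalize = FALSE`.
#' @param normalize Apply [normalize_text()] to both inputs (default `TRUE`).
#' @return Numeric vector of scores in \[0, 100\].
#' @examples
#' word_overlap_pwc("the big blue house is for sale",
#'                  "the hous is for sale") # 4/7 * 100
#' @export
word_overlap_pwc <- function(target, response, normalize = TRUE) {
  p <- .pair_recycle(target, response)
  a <- p$a; b <- p$b
  if (normalize) {
    a <- normalize_text(a)
    b <- normalize_text(b)
  }
  ta <- tokenize(a); tb <- tokenize(b)
  mapply(function(x, y) {
    if (length(x) == 0L)
      stop("word_overlap_pwc() is undefined for an empty target")
    shared <- 0L
    ycnt <- table(y)
    xcnt <- table(x)
    common <- intersect(names(xcnt), names(ycnt))
    if (length(common))
      shared <- sum(pmin(xcnt[common], ycnt[common]))
    100 * shared / length(x)
  }, ta, tb, USE.NAMES = FALSE)
}
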