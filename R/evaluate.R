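#' Pearson product-moment correlation with explicit degenerate-input errors
#'
#' Thin wrapper around [stats::cor()] that enforces the preconditions a
#' metric-evaluation table needs: equal lengths, at least three
#' observations, and non-constant inputs (a constant sequence has no defined
#' correlation and errors instead of silently returning `NA` or 0).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A single correlation in \[-1, 1\].
#' @examples
#' pearson_r(1:5, 2 * (1:5) + 1) # 1
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 3)
    stop("need at least 3 observations for a correlation")
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation is undefined for a constant input")
  stats::cor(x, y)
}

#' Correlate transcript metrics with a reference score
#'
#' The desk-scale analogue of validating automated metrics against human
#' scores: for each metric column present in a scored corpus, computes the
#' Pearson correlation with a reference column and checks that its sign
#' matches expectation — negative for the distance metrics (`LS_score`,
#' `Jaro_score`, where larger means worse) and positive for the similarity
#' scores (`TSR_score`, `PWC_auto`).
#'
#' @param corpus Data frame containing the reference column and at least one
#'   of `TSR_score`, `LS_score`, `Jaro_score`, `PWC_auto` (e.g. the output
#'   of [score_strings] columns bound to a [simulate_corpus()] table).
#' @param reference Name of the reference column (default
#'   `"true_report_fraction"`).
#' @return A data frame with one row per metric: `metric`, `r`, `n`,
#'   `expected_sign` (`"+"` or `"-"`), `sign_ok`.
#' @examples
#' corpus <- simulate_corpus(50, seed = 3)
#' scored <- cbind(corpus, score_pair(corpus$target, corpus$response)[-(1:4)])
#' evaluate_metrics(scored)
#' @export
evaluate_metrics <- function(corpus, reference = "true_report_fraction") {
  if (!reference %in% names(corpus))
    stop("reference column '", reference, "' not found")
  expected <- c(LS_score = "-", Jaro_score = "-",
                TSR_score = "+", PWC_auto = "+")
  metrics <- intersect(names(expected), names(corpus))
  if (length(metrics) == 0)
    stop("no metric columns found in corpus")
  ref <- as.numeric(corpus[[reference]])
  rows <- lapply(metrics, function(m) {
    r <- tryCatch(pearson_r(corpus[[m]], ref),
                  error = function(e)
                    stop("metric '", m, "': ", conditionMessage(e),
                         call. = FALSE))
    sign_ok <- if (expected[[m]] == "+") r > 0 else r < 0
    data.frame(metric = m, r = r, n = length(ref),
               expected_sign = expected[[m]], sign_ok = sign_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
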