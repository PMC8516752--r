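#' Score one target/response pair with all metrics
#'
#' Normalizes both strings exactly once, then computes every requested
#' metric on the normalized forms. This is the single-pair view of the
#' batch scorer in [score_file()].
#'
#' @param target,response Raw strings (may be empty or `NA`; `NA` counts as
#'   an empty response).
#' @param metrics Character vector choosing which metrics to compute, any of
#'   `"tsr"`, `"levenshtein"`, `"jaro"`, `"pwc"`.
#' @param count_spaces,round_score Passed to [token_sort_ratio()].
#' @param remove_punctuation,lowercase Normalization switches, passed to
#'   [normalize_text()].
#' @return A one-row data frame with columns `target`, `response`,
#'   `target_norm`, `response_norm` and one column per requested metric:
#'   `TSR_score` (0–100), `LS_score` (edit operations), `Jaro_score` (0–1),
#'   `PWC_auto` (0–100; `NA` when the normalized target is empty).
#' @examples
#' score_pair("water", "wayer")
#' @export
score_pair <- function(target, response,
                       metrics = c("tsr", "levenshtein", "jaro", "pwc"),
                       count_spaces = TRUE, round_score = FALSE,
                       remove_punctuation = TRUE, lowercase = TRUE) {
  df <- score_strings(target, response, metrics = metrics,
                      count_spaces = count_spaces, round_score = round_score,
                      remove_punctuation = remove_punctuation,
                      lowercase = lowercase)
  df
}

# Vectorized scoring core shared by score_pair() and score_file().
score_strings <- function(target, response,
                          metrics = c("tsr", "levenshtein", "jaro", "pwc"),
                          count_spaces = TRUE, round_score = FALSE,
                          remove_punctuation = TRUE, lowercase = TRUE) {
  metrics <- match.arg(metrics, c("tsr", "levenshtein", "jaro", "pwc"),
                       several.ok = TRUE)
  p <- .pair_recycle(target, response)
  tn <- normalize_text(p$a, remove_punctuation = remove_punctuation,
                       lowercase = lowercase)
  rn <- normalize_text(p$b, remove_punctuation = remove_punctuation,
                       lowercase = lowercase)
  out <- data.frame(target = p$a, response = p$b,
                    target_norm = tn, response_norm = rn,
                    stringsAsFactors = FALSE)
  if ("tsr" %in% metrics)
    out$TSR_score <- token_sort_ratio(tn, rn, count_spaces = count_spaces,
                                      round_score = round_score,
                                      normalize = FALSE)
  if ("levenshtein" %in% metrics)
    out$LS_score <- levenshtein(tn, rn)
  if ("jaro" %in% metrics)
    out$Jaro_score <- jaro_distance(tn, rn)
  if ("pwc" %in% metrics) {
    out$PWC_auto <- NA_real_
    ok <- nzchar(tn)
    if (any(ok))
      out$PWC_auto[ok] <- word_overlap_pwc(tn[ok], rn[ok],
                                           normalize = FALSE)
  }
  out
}

#' Batch-score a CSV file of targets and responses
#'
#' Reads a UTF-8 CSV with (at minimum) columns named exactly `target` and
#' `response`, computes the requested metrics for every row, and writes the
#' same table extended with the metric columns — `TSR_score` always first,
#' then `LS_score`, `Jaro_score`, `PWC_auto` when requested. All input
#' columns, cell contents, and row order are preserved verbatim. Missing or
#' empty response cells are scored as empty strings (TSR 0); their count is
#' reported in the run summary.
#'
#' @param input_path Path to the input CSV (RFC 4180, UTF-8; a BOM is
#'   tolerated on read, never written).
#' @param output_path Path for the scored CSV.
#' @param metrics,count_spaces,round_score,remove_punctuation,lowercase
#'   Passed to the scorer; see [score_pair()].
#' @param quiet Suppress the run summary on standard error.
#' @return Invisibly, a list with `rows_read`, `rows_scored`,
#'   `empty_responses`, and the output path.
#' @examples
#' tmp_in <- tempfile(fileext = ".csv")
#' writeLines(c("target,response", "water,wayer"), tmp_in)
#' tmp_out <- tempfile(fileext = ".csv")
#' score_file(tmp_in, tmp_out, quiet = TRUE)
#' read.csv(tmp_out)
#' @export
score_file <- function(input_path, output_path,
                       metrics = "tsr",
                       count_spaces = TRUE, round_score = FALSE,
                       remove_punctuation = TRUE, lowercase = TRUE,
                       quiet = FALSE) {
  if (!file.exists(input_path))
    stop("input file not found: ", input_path)
  # parsing issues surface as a hard error below, not a readr warning
  df <- suppressWarnings(
    readr::read_csv(input_path,
                    col_types = readr::cols(.default = readr::col_character()),
                    na = character(), progress = FALSE,
                    locale = readr::locale(encoding = "UTF-8")))
  probs <- readr::problems(df)
  if (nrow(probs) > 0)
    stop("malformed CSV input (first problem at row ", probs$row[1], "): ",
         probs$expected[1], " vs ", probs$actual[1])
  for (col in c("target", "response"))
    if (!col %in% names(df))
      stop("input is missing required column '", col, "'")
  scored <- score_strings(df$target, df$response, metrics = metrics,
                          count_spaces = count_spaces,
                          round_score = round_score,
                          remove_punctuation = remove_punctuation,
                          lowercase = lowercase)
  out <- df
  for (col in c("TSR_score", "LS_score", "Jaro_score", "PWC_auto"))
    if (col %in% names(scored)) {
      if (col %in% names(out))
        stop("input already has a column named '", col,
             "'; rename it before scoring")
      out[[col]] <- scored[[col]]
    }
  readr::write_csv(out, output_path, na = "", progress = FALSE)
  summary <- list(rows_read = nrow(df), rows_scored = nrow(scored),
                  empty_responses = sum(!nzchar(df$response)),
                  output = output_path)
  if (!quiet)
    message(sprintf("scored %d rows (%d empty responses) -> %s",
                    summary$rows_scored, summary$empty_responses,
                    output_path))
  invisible(summary)
}
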