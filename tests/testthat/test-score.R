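test_that("pair scoring computes all metrics on normalized forms", {
  rec <- score_pair("water", "wayer")
  expect_equal(rec$TSR_score, 80)
  expect_identical(rec$LS_score, 1L)
  expect_equal(round(rec$Jaro_score, 3), 0.133)
  expect_equal(rec$PWC_auto, 0)
  rec <- score_pair("Water.", "water")
  expect_equal(rec$TSR_score, 100)
  expect_identical(rec$LS_score, 0L)
  expect_equal(rec$PWC_auto, 100)
  rec <- score_pair("Mary saw John", "John saw Mary")
  expect_equal(rec$TSR_score, 100)
  expect_gt(rec$LS_score, 0)
  # empty normalized target has no defined word-overlap score
  expect_true(is.na(score_pair("!!!", "water")$PWC_auto))
})

test_that("CSV batch scoring appends metric columns and preserves input", {
  input <- tempfile(fileext = ".csv")
  output <- tempfile(fileext = ".csv")
  writeLines(c(
    "id,target,response,note",
    "1,water,wayer,typo",
    "2,The big blue house is for sale,the hous is for sale,partial",
    "3,water,,missed",
    "4,\"a, b\",a b,quoted"), input)
  res <- score_file(input, output, metrics = c("tsr", "levenshtein", "jaro",
                                               "pwc"), quiet = TRUE)
  expect_identical(res$rows_read, 4L)
  expect_identical(res$empty_responses, 1L)
  out <- readr::read_csv(output, show_col_types = FALSE, na = character())
  expect_identical(names(out),
                   c("id", "target", "response", "note", "TSR_score",
                     "LS_score", "Jaro_score", "PWC_auto"))
  expect_equal(out$TSR_score, c(80, 80, 0, 100))
  expect_identical(out$note, c("typo", "partial", "missed", "quoted"))
  # row order and cells preserved; scoring a scored file keeps prior
  # columns byte-identical
  output2 <- tempfile(fileext = ".csv")
  input2 <- tempfile(fileext = ".csv")
  # drop the TSR column name clash by renaming on the way through
  tab <- readr::read_csv(output, show_col_types = FALSE, na = character())
  names(tab)[names(tab) == "TSR_score"] <- "TSR_prev"
  names(tab)[names(tab) == "LS_score"] <- "LS_prev"
  names(tab)[names(tab) == "Jaro_score"] <- "Jaro_prev"
  names(tab)[names(tab) == "PWC_auto"] <- "PWC_prev"
  readr::write_csv(tab, input2)
  score_file(input2, output2, metrics = "tsr", quiet = TRUE)
  before <- readr::read_csv(input2, show_col_types = FALSE, na = character())
  after <- readr::read_csv(output2, show_col_types = FALSE, na = character())
  expect_identical(before, after[names(before)])
  # re-running is deterministic down to the bytes
  output3 <- tempfile(fileext = ".csv")
  score_file(input2, output3, metrics = "tsr", quiet = TRUE)
  expect_identical(readLines(output2), readLines(output3))
})

test_that("packaged worked-examples fixture reproduces the golden scores", {
  fixture <- system.file("extdata", "worked_examples.csv",
                         package = "fuzzscore")
  output <- tempfile(fileext = ".csv")
  score_file(fixture, output, quiet = TRUE)
  out <- readr::read_csv(output, show_col_types = FALSE, na = character())
  expect_identical(out$item, c("A1", "A2", "A3", "B1", "B2", "B3"))
  # B3: sorted target vs "sail" share "sa" and "l", M = 3, T = 34
  expect_equal(out$TSR_score, c(100, 80, 0, 100, 80, 300 / 17))
})

test_that("CSV errors are hard and informative", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sentence,reply", "water,wayer"), f)
  out <- tempfile(fileext = ".csv")
  expect_error(score_file(f, out, quiet = TRUE), "target")
  writeLines(c("target,response", "water,wayer,extra,cols"), f)
  expect_error(score_file(f, out, quiet = TRUE), "malformed CSV")
  expect_error(score_file(tempfile(), out, quiet = TRUE), "not found")
  writeLines(c("target,response,TSR_score", "water,wayer,1"), f)
  expect_error(score_file(f, out, quiet = TRUE), "TSR_score")
})

test_that("batch scoring of thousands of rows stays fast", {
  corpus <- simulate_corpus(2000, seed = 77)
  input <- tempfile(fileext = ".csv")
  output <- tempfile(fileext = ".csv")
  readr::write_csv(corpus[c("target", "response")], input)
  elapsed <- system.time(
    score_file(input, output, metrics = c("tsr", "levenshtein", "jaro",
                                          "pwc"), quiet = TRUE))["elapsed"]
  expect_lt(elapsed, 60)
  out <- readr::read_csv(output, show_col_types = FALSE)
  expect_identical(nrow(out), 2000L)
  expect_true(all(out$TSR_score >= 0 & out$TSR_score <= 100))
  expect_true(all(out$Jaro_score >= 0 & out$Jaro_score <= 1))
})
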