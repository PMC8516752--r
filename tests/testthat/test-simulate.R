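test_that("target generation is seeded, bounded, and lexicon-driven", {
  t1 <- generate_targets(3, c(5, 5), seed = 42)
  t2 <- generate_targets(3, c(5, 5), seed = 42)
  expect_identical(t1, t2)
  expect_true(all(lengths(tokenize(t1)) == 5))
  lens <- lengths(tokenize(generate_targets(1000, c(5, 20), seed = 1)))
  expect_true(all(lens >= 5 & lens <= 20))
  expect_false(identical(generate_targets(10, c(5, 20), seed = 1),
                         generate_targets(10, c(5, 20), seed = 2)))
  expect_error(generate_targets(5, c(5, 20), lexicon = character(0)),
               "lexicon")
  words <- unlist(tokenize(generate_targets(50, c(5, 10), seed = 9)))
  expect_true(all(words %in% default_lexicon()))
})

test_that("identity settings return the target verbatim", {
  model <- error_model(report_prob = 1, typo_rate = 0, shuffle_prob = 0,
                       intrusion_rate = 0)
  set.seed(5)
  rec <- corrupt_response("the big blue house is for sale", model)
  expect_identical(rec$response, rec$target)
  expect_identical(rec$true_report_fraction, 1)
  expect_identical(rec$n_typos, 0L)
  model0 <- error_model(report_prob = 0, typo_rate = 0, shuffle_prob = 0,
                        intrusion_rate = 0)
  rec <- corrupt_response("the big blue house is for sale", model0)
  expect_identical(rec$response, "")
  expect_identical(rec$true_report_fraction, 0)
  expect_equal(token_sort_ratio(rec$target, rec$response), 0)
})

test_that("typos substitute adjacent keys only", {
  adj <- qwerty_adjacency()
  expect_setequal(adj[["t"]], c("r", "y", "f", "g"))
  # force a typo on every character: each output char is a neighbour
  model <- error_model(report_prob = 1, typo_rate = 1, shuffle_prob = 0,
                       intrusion_rate = 0)
  set.seed(11)
  rec <- corrupt_response("water", model)
  expect_identical(rec$n_typos, 5L)
  out <- strsplit(rec$response, "")[[1]]
  src <- strsplit("water", "")[[1]]
  for (i in seq_along(src))
    expect_true(out[i] %in% adj[[src[i]]])
  # the 'wayer'-style single substitution is reachable
  third <- vapply(1:200, function(k) {
    set.seed(k)
    m <- error_model(report_prob = 1, typo_rate = 1, shuffle_prob = 0,
                     intrusion_rate = 0)
    substr(corrupt_response("water", m)$response, 3, 3)
  }, character(1))
  expect_true(all(third %in% c("r", "y", "g", "f")))
  expect_true("y" %in% third)
})

test_that("corpus simulation is reproducible and calibrated", {
  c1 <- simulate_corpus(50, seed = 123)
  c2 <- simulate_corpus(50, seed = 123)
  expect_identical(c1, c2)
  expect_false(identical(c1, simulate_corpus(50, seed = 124)))
  expect_true(all(c1$true_report_fraction >= 0 &
                    c1$true_report_fraction <= 1))
  # mean report fraction within 3 standard errors of the report probability
  model <- error_model(report_prob = 0.7, typo_rate = 0, shuffle_prob = 0,
                       intrusion_rate = 0)
  corpus <- simulate_corpus(1000, model, seed = 19)
  n_words <- sum(lengths(tokenize(corpus$target)))
  se <- sqrt(0.7 * 0.3 / n_words)
  frac <- sum(lengths(tokenize(corpus$response))) / n_words
  expect_lt(abs(frac - 0.7), 3 * se)
})

test_that("with only omissions, word overlap equals the report fraction", {
  model <- error_model(report_prob = c(0, 1), typo_rate = 0,
                       shuffle_prob = 0, intrusion_rate = 0)
  corpus <- simulate_corpus(200, model, seed = 8)
  pwc <- word_overlap_pwc(corpus$target, corpus$response)
  expect_equal(pwc, 100 * corpus$true_report_fraction)
})

test_that("mean TSR increases with the report probability", {
  mean_tsr <- function(p, seed) {
    m <- error_model(report_prob = p, typo_rate = 0.05, shuffle_prob = 0.1,
                     intrusion_rate = 0.5)
    corpus <- simulate_corpus(200, m, seed = seed)
    mean(token_sort_ratio(corpus$target, corpus$response))
  }
  lo <- mean_tsr(0.1, 31)
  mid <- mean_tsr(0.5, 31)
  hi <- mean_tsr(0.9, 31)
  expect_gt(mid, lo)
  expect_gt(hi, mid)
})

test_that("intrusions come from outside the target and model validates", {
  model <- error_model(report_prob = 1, typo_rate = 0, shuffle_prob = 0,
                       intrusion_rate = 3)
  set.seed(77)
  target <- "water house green"
  rec <- corrupt_response(target, model)
  extra <- setdiff(tokenize(rec$response)[[1]], tokenize(target)[[1]])
  expect_true(all(extra %in% default_lexicon()))
  expect_false(any(extra %in% tokenize(target)[[1]]))
  expect_identical(rec$true_report_fraction, 1)
  expect_error(error_model(report_prob = 1.5), "report_prob")
  expect_error(error_model(typo_rate = -0.1))
})
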