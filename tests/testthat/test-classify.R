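micro <- tibble::tibble(class = rep(c("c1", "c2"), c(3, 2)),
                        f1 = c(0, 1, 4, 10, 12))

make_match <- function(final, queries, F_ = 1) {
  structure(list(final = final, queries = queries,
                 n_final = F_, n_query = nrow(queries[[1]]),
                 feature_names = sprintf("f%d", seq_len(ncol(final[[1]]))),
                 config = iatr_config(K = 1)),
            class = "iatr_match")
}

test_that("worked example: both pooled queries vote for the nearer class", {
  res <- iatr_predict(micro, 3, iatr_config(K = 2, n_final = 1))
  expect_equal(res$decision, "c1")
  expect_equal(res$votes$vote_fraction, c(1, 0))
  expect_equal(res$votes$score, c(2, 7))
  expect_false(res$tie_broken)
  expect_equal(res$assignments$assigned, c("c1", "c1"))
})

test_that("majority vote follows the assignment counts", {
  # six pooled vectors, four nearest to class a -> decision a with 4/6
  final <- list(a = matrix(0, 1, 1), b = matrix(10, 1, 1))
  queries <- list(a = matrix(c(0, 1, 2), 3, 1),
                  b = matrix(c(3, 9, 10), 3, 1))
  res <- iatr_classify(make_match(final, queries))
  expect_equal(res$assignments$assigned, c("a", "a", "a", "a", "b", "b"))
  expect_equal(res$decision, "a")
  expect_equal(res$votes$vote_fraction, c(4 / 6, 2 / 6))
  expect_equal(sum(res$votes$vote_fraction), 1)
})

test_that("a vote tie is broken by the smallest class score", {
  final <- list(a = matrix(0, 1, 1), b = matrix(10, 1, 1))
  queries <- list(a = matrix(0.1, 1, 1), b = matrix(9.5, 1, 1))
  res <- iatr_classify(make_match(final, queries))
  expect_true(res$tie_broken)
  expect_equal(res$decision, "a")         # scores 0.1 vs 0.5
  expect_equal(res$votes$score, c(0.1, 0.5))
})

test_that("argmin ties in assignment go to the lower class index", {
  final <- list(a = matrix(1, 1, 1), b = matrix(3, 1, 1))
  queries <- list(a = matrix(2, 1, 1), b = matrix(2, 1, 1))
  res <- iatr_classify(make_match(final, queries))
  expect_equal(res$assignments$assigned, c("a", "a"))
})

test_that("tidy and glance summarize the decision", {
  res <- iatr_predict(micro, 3, iatr_config(K = 2, n_final = 1))
  expect_equal(tidy(res), res$votes)
  g <- glance(res)
  expect_equal(g$decision, "c1")
  expect_equal(g$score, 2)
})

test_that("verification scores are the within-class reconstructed distances", {
  sc <- iatr_verification_scores(micro, 3, iatr_config(K = 2, n_final = 1))
  expect_equal(sc$score, c(2, 7))
  # identical query reproduces a zero score for its class
  tm <- iatr_train(micro, iatr_config(K = 2, n_final = 1))
  sc0 <- iatr_verification_scores(iatr_match(tm, 1))
  expect_equal(sc0$score[1], 0)
  expect_true(all(sc0$score >= 0))
})

test_that("end-to-end prediction equals the staged composition and the oracle", {
  for (seed in 201:215) {
    case <- random_case(seed)
    expect_true(oracle_equivalent(case))
    cfg <- iatr_config(K = case$K, n_final = case$F, n_query = case$S)
    staged <- iatr_classify(iatr_match(iatr_train(mats_to_df(case$mats), cfg),
                                       case$Q))
    direct <- iatr_predict(mats_to_df(case$mats), case$Q, cfg)
    expect_identical(staged, direct)
  }
})

test_that("duplicated well-separated training rows are recovered", {
  set.seed(33)
  d <- gen_gaussian_dataset(4, 6, 5, delta = 50, sigma = 1, seed = 9)
  q <- as.matrix(d[d$class == "c03", -1])[1:2, ]
  res <- iatr_predict(d, q, iatr_config(K = 4, n_final = 2))
  expect_equal(res$decision, "c03")
})
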