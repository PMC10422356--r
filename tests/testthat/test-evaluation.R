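test_that("cmc counts ranks exhaustively with worst-case ties", {
  s <- rbind(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
  colnames(s) <- c("a", "b", "c")
  # true-class scores are 1, 3, 3 -> ranks 1, 3, 3
  curve <- cmc(s, c("a", "c", "a"))
  expect_equal(curve$accuracy, c(1 / 3, 1 / 3, 1))
  expect_true(all(diff(curve$accuracy) >= 0))
  expect_equal(curve$accuracy[3], 1)
  # tied scores count against the true class
  tied <- matrix(c(1, 1, 2), 1, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(cmc(tied, "a")$accuracy, c(0, 1, 1))
  expect_error(cmc(s[0, , drop = FALSE], character()), "empty")
})

test_that("det_eer handles separation, overlap and identity", {
  expect_equal(det_eer(c(1, 2), c(5, 6))$eer, 0)
  g <- c(1, 2, 3, 4)
  expect_equal(det_eer(g, g)$eer, 50)
  expect_equal(det_eer(c(1, 2, 9), c(3, 8, 10))$eer, 100 / 3)
  expect_error(det_eer(numeric(), 1), "nonempty")
})

test_that("det_eer agrees with an exhaustive quadratic threshold sweep", {
  for (seed in 1:8) {
    set.seed(seed)
    g <- round(rnorm(sample(5:100, 1)), 2)
    i <- round(rnorm(sample(5:100, 1), mean = 1.5), 2)
    res <- det_eer(g, i)
    # brute force: evaluate every candidate threshold independently
    best <- Inf; eer <- NA
    for (t in c(min(c(g, i)) - 1, sort(c(g, i)))) {
      far <- sum(i <= t) / length(i)
      frr <- sum(g > t) / length(g)
      if (abs(far - frr) < best) {
        best <- abs(far - frr)
        eer <- 100 * (far + frr) / 2
      }
    }
    expect_equal(res$eer, eer)
    expect_true(all(res$sweep$far >= 0 & res$sweep$far <= 1))
    expect_true(all(res$sweep$frr >= 0 & res$sweep$frr <= 1))
    expect_true(all(diff(res$sweep$far) >= 0))
    expect_true(all(diff(res$sweep$frr) <= 0))
    expect_gte(res$eer, 0); expect_lte(res$eer, 50)
  }
})

test_that("nearest-neighbour baseline votes by nearest training row", {
  d <- tibble::tibble(class = c("a", "b"), f1 = c(0, 10), f2 = c(0, 10))
  expect_equal(nn_baseline(d, c(1, 1)), "a")
  expect_equal(nn_baseline(d, c(10, 10)), "b")
  set.seed(12)
  d2 <- gen_gaussian_dataset(4, 5, 3, delta = 8, sigma = 1, seed = 5)
  q <- as.matrix(d2[7, -1])
  expect_equal(nn_baseline(d2, q), d2$class[7])
  shuffled <- d2[sample(nrow(d2)), ]
  expect_equal(nn_baseline(shuffled, q), d2$class[7])
  expect_error(nn_baseline(d[0, ], 1), "class labels|at least")
})

test_that("identification on separated self-queries is perfect with diagonal confusion", {
  d <- gen_gaussian_dataset(4, 8, 5, delta = 30, sigma = 1, seed = 21)
  queries <- lapply(unique(d$class), function(cl) {
    list(query = as.matrix(d[d$class == cl, -1])[1:2, ], class = cl)
  })
  res <- identification_experiment(d, queries, iatr_config())
  expect_equal(res$accuracy, 1)
  expect_true(all(res$confusion[upper.tri(res$confusion)] == 0))
  expect_true(all(res$confusion[lower.tri(res$confusion)] == 0))
  expect_equal(unname(diag(res$confusion)), rep(1L, 4))
  wide <- iatr:::score_table_wide(res$score_table)
  curve <- cmc(wide$scores, wide$truth)
  expect_equal(curve$accuracy[1], 1)
  gi <- genuine_impostor(res$score_table)
  expect_length(gi$genuine, 4)
  expect_length(gi$impostor, 12)
  expect_equal(det_eer(gi$genuine, gi$impostor)$eer, 0)
})

test_that("fold rotation holds each recording block out exactly once", {
  d <- gen_gaussian_dataset(3, 9, 4, delta = 25, sigma = 1, seed = 31)
  res <- identification_experiment(d, config = iatr_config(), folds = 3)
  expect_equal(sum(res$confusion), 9L)        # 3 folds x 3 classes
  expect_equal(length(unique(res$score_table$event)), 9L)
  expect_equal(res$accuracy, 1)
  g <- glance(res)
  expect_named(g, c("accuracy", "rank1", "eer"))
  expect_error(identification_experiment(d, folds = 1), "folds")
  expect_error(identification_experiment(d), "queries or folds")
})

test_that("result plots are well-formed ggplot objects", {
  s <- rbind(c(1, 2), c(2, 1)); colnames(s) <- c("a", "b")
  expect_s3_class(ggplot2::autoplot(cmc(s, c("a", "b"))), "ggplot")
  expect_s3_class(ggplot2::autoplot(det_eer(c(1, 2), c(2, 3))), "ggplot")
  d <- tibble::tibble(class = rep(c("a", "b"), c(3, 2)),
                      f1 = c(0, 1, 4, 10, 12))
  expect_s3_class(ggplot2::autoplot(iatr_predict(d, 3, iatr_config(K = 2))),
                  "ggplot")
})
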