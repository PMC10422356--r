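micro <- tibble::tibble(class = rep(c("c1", "c2"), c(3, 2)),
                        f1 = c(0, 1, 4, 10, 12))

test_that("training phase retains the best-separated elements per dimension", {
  tm <- iatr_train(micro, iatr_config(K = 2, n_final = 1))
  expect_equal(unname(tm$templates$c1), matrix(c(0, 1), 2, 1))
  expect_equal(unname(tm$templates$c2), matrix(c(12, 10), 2, 1))
  expect_equal(unname(tm$provenance$c1), matrix(c(1L, 2L), 2, 1))
  expect_equal(unname(tm$provenance$c2), matrix(c(2L, 1L), 2, 1))
})

test_that("full retention gives a per-dimension permutation of the input", {
  set.seed(21)
  mats <- list(matrix(rnorm(15), 5, 3), matrix(rnorm(15), 5, 3))
  tm <- iatr_train(mats_to_df(mats), iatr_config(K = 5))
  for (n in 1:2) {
    for (l in 1:3) {
      expect_equal(sort(tm$templates[[n]][, l]), sort(mats[[n]][, l]))
    }
  }
})

test_that("ties in separation keep original instance order", {
  d <- tibble::tibble(class = rep(c("a", "b"), each = 3),
                      f1 = rep(c(1, 2), each = 3))  # all D equal per class
  tm <- iatr_train(d, iatr_config(K = 2))
  expect_equal(unname(tm$provenance$a), matrix(c(1L, 2L), 2, 1))
  expect_equal(unname(tm$provenance$b), matrix(c(1L, 2L), 2, 1))
})

test_that("K resolution: ratio default, explicit clamp with warning, K < 1 rejected", {
  set.seed(3)
  mats <- list(matrix(rnorm(18), 9, 2), matrix(rnorm(12), 6, 2))
  d <- mats_to_df(mats)
  tm <- iatr_train(d)                       # P = 2/3
  expect_equal(unname(tm$K), c(round(2 / 3 * 9), round(2 / 3 * 6)))
  expect_warning(tm2 <- iatr_train(d, iatr_config(K = 8)), "clamped")
  expect_equal(unname(tm2$K), c(8L, 6L))
  expect_error(iatr_config(K = 0), "K must be")
})

test_that("templates stay inside the per-class bounding box", {
  for (seed in 1:15) {
    case <- random_case(seed)
    tm <- iatr_train(mats_to_df(case$mats), iatr_config(K = case$K))
    for (n in seq_along(case$mats)) {
      lo <- apply(case$mats[[n]], 2, min)
      hi <- apply(case$mats[[n]], 2, max)
      expect_true(all(sweep(tm$templates[[n]], 2, lo, `>=`)))
      expect_true(all(sweep(tm$templates[[n]], 2, hi, `<=`)))
    }
  }
})

test_that("retained elements have separation at least the class average", {
  for (seed in 1:15) {
    case <- random_case(seed)
    D <- oracle_separation(case$mats)
    tm <- iatr_train(mats_to_df(case$mats), iatr_config(K = case$K))
    for (n in seq_along(case$mats)) {
      for (l in seq_len(ncol(case$mats[[n]]))) {
        kept <- tm$provenance[[n]][, l]
        expect_gte(mean(D[[n]][kept, l]), mean(D[[n]][, l]) - 1e-12)
      }
    }
  }
})

test_that("tidy() exposes values with their provenance", {
  tm <- iatr_train(micro, iatr_config(K = 2))
  td <- tidy(tm)
  expect_named(td, c("class", "template", "dimension", "value",
                     "source_instance"))
  expect_equal(nrow(td), 4)
  orig <- c(0, 1, 4, 10, 12)
  expect_true(all(td$value %in% orig))
})
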