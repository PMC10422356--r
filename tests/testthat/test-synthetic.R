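test_that("gaussian generator is balanced, reproducible and leaves the RNG alone", {
  d <- gen_gaussian_dataset(5, 7, 4, delta = 10, sigma = 1, seed = 3)
  expect_equal(dim(d), c(35L, 5L))
  expect_equal(unname(table(d$class)), rep(7L, 5), ignore_attr = TRUE)
  expect_identical(d, gen_gaussian_dataset(5, 7, 4, delta = 10, sigma = 1,
                                           seed = 3))
  set.seed(99); before <- rnorm(1)
  set.seed(99); gen_gaussian_dataset(3, 2, 2, seed = 5); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero noise collapses every instance onto its class centre", {
  d <- gen_gaussian_dataset(4, 3, 6, delta = 5, sigma = 0, seed = 2)
  ctr <- attr(d, "centers")
  for (i in seq_len(4)) {
    rows <- as.matrix(d[d$class == sprintf("c%02d", i), -1])
    expect_equal(rows, matrix(ctr[i, ], 3, 6, byrow = TRUE),
                 ignore_attr = TRUE)
  }
  # centres lie on the sphere of radius delta, mutually delta*sqrt(2) apart
  expect_equal(unname(sqrt(rowSums(ctr^2))), rep(5, 4))
  expect_equal(unname(as.vector(dist(ctr))), rep(5 * sqrt(2), 6),
               tolerance = 1e-12)
})

test_that("empirical within-class variance approaches sigma^2", {
  d <- gen_gaussian_dataset(2, 1e4, 3, delta = 8, sigma = 1.5, seed = 8)
  v <- unlist(lapply(split(d[-1], d$class), function(m) apply(m, 2, var)))
  expect_true(all(abs(v - 1.5^2) / 1.5^2 < 0.05))
})

test_that("session drift offsets exactly the chosen dimensions by gamma", {
  d <- gen_gaussian_dataset(3, 5, 8, delta = 6, sigma = 1, seed = 10)
  d0 <- apply_session_drift(d, gamma = 0, seed = 1)
  expect_equal(tibble::as_tibble(d0), tibble::as_tibble(d),
               ignore_attr = TRUE)
  dr <- apply_session_drift(d, gamma = 3, rho = 0.5, seed = 1)
  off <- attr(dr, "drift")
  expect_equal(dim(off), c(3L, 8L))
  for (cl in rownames(off)) {
    drifted <- which(off[cl, ] != 0)
    expect_length(drifted, ceiling(0.5 * 8))
    expect_true(all(abs(off[cl, drifted]) == 3))
    rows <- d$class == cl
    for (j in seq_len(8)) {
      expect_equal(dr[rows, j + 1, drop = TRUE],
                   d[rows, j + 1, drop = TRUE] + off[cl, j])
    }
  }
})

test_that("toy images are deterministic shapes clipped to [0, 255]", {
  imgs <- gen_toy_images(10, 3, size = 16, noise = 0, seed = 1)
  expect_equal(nrow(imgs), 30)
  by_class <- split(imgs$image, imgs$class)
  for (set in by_class) {
    expect_identical(set[[1]], set[[2]])
    expect_identical(set[[2]], set[[3]])
  }
  noisy <- gen_toy_images(4, 2, size = 16, noise = 60, seed = 2)
  allv <- unlist(noisy$image)
  expect_true(all(allv >= 0 & allv <= 255))
  expect_false(identical(noisy$image[[1]], noisy$image[[2]]))
  expect_error(gen_toy_images(40, 1), "shape families")
  expect_error(gen_toy_images(2, 1, size = 4), "size")
})

test_that("toy image classes are separable by the template classifier", {
  imgs <- gen_toy_images(6, 7, size = 16, noise = 40, seed = 5)
  train <- dplyr::bind_rows(purrr::map2(imgs$class, imgs$image, function(cl, im) {
    dplyr::bind_cols(tibble::tibble(class = cl),
                     image_query_set(im, copies = 0))
  }))
  probe <- gen_toy_images(6, 1, size = 16, noise = 40, seed = 77)
  correct <- 0L
  for (i in seq_len(6)) {
    q <- image_query_set(probe$image[[i]], copies = 1, seed = 80 + i)
    res <- iatr_predict(train, q, iatr_config())
    correct <- correct + (res$decision == probe$class[i])
  }
  expect_gte(correct, 5L)
})

test_that("band-limited noise concentrates its power inside the pass band", {
  fs <- 160
  x <- gen_band_signal(fs * 40, fs, c(32, 38), seed = 6)
  feats <- wpd_variance_features(x[seq_len(640)], eeg_config(fs = fs))
  expect_equal(unname(which.max(feats)), 4L)   # 30-40 Hz band
  expect_identical(gen_band_signal(100, fs, c(5, 15), seed = 3),
                   gen_band_signal(100, fs, c(5, 15), seed = 3))
  expect_error(gen_band_signal(100, fs, c(0, 200)), "band")
})
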