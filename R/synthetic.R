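#' Generate a Gaussian class-cluster feature table
#'
#' Class centres are drawn on a sphere of radius `delta`: for
#' `n_classes <= n_dims` they are random orthonormal directions (QR of a
#' seeded Gaussian matrix) scaled by `delta`, so every pair of centres
#' is exactly `delta * sqrt(2)` apart and the difficulty is controlled
#' by the single ratio `delta / sigma`; with more classes than
#' dimensions they fall back to independent random directions.
#' Instances are the centre plus isotropic Gaussian noise of standard
#' deviation `sigma`.  Classes are balanced.
#'
#' @param n_classes,n_per_class,n_dims counts (N, I, L).
#' @param delta centre dispersion scale.
#' @param sigma within-class standard deviation (>= 0).
#' @param seed optional seed; generation is a pure function of the
#'   arguments and the seed.
#' @param centers optional `n_classes x n_dims` matrix of centres to
#'   reuse (e.g. to draw a second session from the same population).
#' @return tibble with a `class` column (`c01`, `c02`, ...) and
#'   `f1..fL` feature columns, `n_classes * n_per_class` rows; the
#'   centre matrix is attached as attribute `"centers"`.
#' @examples
#' d <- gen_gaussian_dataset(3, 5, 4, delta = 10, sigma = 1, seed = 1)
#' dplyr::count(d, class)
#' @export
gen_gaussian_dataset <- function(n_classes = 10, n_per_class = 40,
                                 n_dims = 12, delta = 10, sigma = 1,
                                 seed = NULL, centers = NULL) {
  if (n_classes < 1 || n_per_class < 1 || n_dims < 1) {
    abort("n_classes, n_per_class and n_dims must all be >= 1")
  }
  if (sigma < 0) abort("sigma must be >= 0")
  with_local_seed(seed, {
    if (is.null(centers)) {
      if (n_classes <= n_dims) {
        g <- matrix(rnorm(n_dims * n_classes), n_dims, n_classes)
        dirs <- t(qr.Q(qr(g)))           # orthonormal rows
      } else {
        g <- matrix(rnorm(n_classes * n_dims), n_classes, n_dims)
        dirs <- g / sqrt(rowSums(g^2))
      }
      centers <- delta * dirs
    }
    stopifnot(nrow(centers) == n_classes, ncol(centers) == n_dims)
    labels <- sprintf("c%02d", seq_len(n_classes))
    mat <- centers[rep(seq_len(n_classes), each = n_per_class), ,
                   drop = FALSE] +
      matrix(rnorm(n_classes * n_per_class * n_dims, sd = sigma),
             n_classes * n_per_class, n_dims)
    colnames(mat) <- feature_names(n_dims)
    out <- dplyr::bind_cols(
      tibble::tibble(class = rep(labels, each = n_per_class)),
      tibble::as_tibble(as.data.frame(mat)))
    attr(out, "centers") <- centers
    out
  })
}

#' Apply heterogeneous session drift (template ageing)
#'
#' Emulates the longitudinal drift between recording sessions: for each
#' class, a random subset of `ceiling(rho * L)` feature dimensions
#' receives an additive offset of magnitude `gamma` with a random,
#' class-specific sign; the remaining dimensions are untouched.  Drift
#' that hits only part of the dimensions is exactly the regime in which
#' element-wise template reconstruction can still match on the stable
#' dimensions while whole-vector nearest-neighbour matching degrades.
#'
#' @param data feature table (a `class` column plus numeric features).
#' @param gamma drift magnitude (0 returns the input unchanged).
#' @param rho fraction of dimensions drifted per class, in `[0, 1]`.
#' @param seed optional seed for the drifted-dimension choice and signs.
#' @param class_col name of the label column.
#' @return tibble of the same shape; the per-class offset matrix is
#'   attached as attribute `"drift"`.
#' @export
apply_session_drift <- function(data, gamma, rho = 0.5, seed = NULL,
                                class_col = "class") {
  if (rho < 0 || rho > 1) abort("rho must be in [0, 1]")
  mats <- split_classes(data, class_col)   # validates
  feats <- setdiff(names(data), class_col)
  L <- length(feats)
  out <- tibble::as_tibble(data)
  classes <- names(mats)
  offsets <- matrix(0, length(classes), L,
                    dimnames = list(classes, feats))
  if (gamma != 0 && rho > 0) {
    with_local_seed(seed, {
      for (cl in classes) {
        dims <- sample.int(L, ceiling(rho * L))
        offsets[cl, dims] <- gamma * sample(c(-1, 1), length(dims),
                                            replace = TRUE)
      }
    })
    labels <- as.character(out[[class_col]])
    for (cl in classes) {
      rows <- labels == cl
      for (j in which(offsets[cl, ] != 0)) {
        out[rows, feats[j]] <- out[rows, feats[j], drop = TRUE] +
          offsets[cl, j]
      }
    }
  }
  attr(out, "drift") <- offsets
  out
}

# parametric binary shape families on a size x size grid
toy_shape_families <- function(size) {
  g <- seq_len(size)
  cx <- (size + 1) / 2
  rr <- outer(g - cx, g - cx, function(y, x) sqrt(x^2 + y^2))
  third <- round(size / 3)
  list(
    hbar    = function() {m <- matrix(0, size, size); m[third:(2 * third), ] <- 1; m},
    vbar    = function() {m <- matrix(0, size, size); m[, third:(2 * third)] <- 1; m},
    disc    = function() (rr <= size / 4) * 1,
    ring    = function() (rr <= size / 3 & rr >= size / 5) * 1,
    cross   = function() {m <- matrix(0, size, size)
                          b <- round(size * 0.4):round(size * 0.6)
                          m[b, ] <- 1; m[, b] <- 1; m},
    diagonal = function() (abs(outer(g, g, `-`)) <= size / 10) * 1,
    frame   = function() {m <- matrix(1, size, size)
                          b <- round(size / 5):(size - round(size / 5))
                          m[b, b] <- 0; m},
    checker = function() outer(g, g, function(i, j)
                          (floor((i - 1) / (size / 4)) +
                           floor((j - 1) / (size / 4))) %% 2),
    saltire = function() (pmin(abs(outer(g, g, `-`)),
                               abs(outer(g, rev(g), `-`))) <= size / 10) * 1,
    halfdisc = function() (rr <= size / 3 &
                           outer(g, g, function(y, x) x >= cx)) * 1,
    corner_dots = function() {m <- matrix(0, size, size)
                              q <- round(size / 4)
                              for (y in c(q, size - q)) for (x in c(q, size - q))
                                m[abs(row(m) - y) <= size / 12 &
                                  abs(col(m) - x) <= size / 12] <- 1
                              m},
    gradient_bar = function() {m <- matrix(0, size, size)
                               m[, third:(2 * third)] <- 1
                               m * (row(m) / size)})
}

#' Generate labelled toy images
#'
#' Each class is one parametric shape family (bars, disc, ring, cross,
#' ...) rendered at intensity 255 on a 0 background, plus seeded
#' additive Gaussian noise of standard deviation `noise`, clipped to
#' `[0, 255]`.  A stand-in for small benchmark image sets at desk
#' scale.
#'
#' @param n_classes number of classes (at most the number of shape
#'   families, currently 12).
#' @param n_per_class images per class.
#' @param size image side length in pixels (>= 8).
#' @param noise additive noise standard deviation (0 makes every image
#'   of a class identical).
#' @param seed optional seed.
#' @return tibble with columns `class`, `instance` and a list-column
#'   `image` of `size x size` matrices.
#' @export
gen_toy_images <- function(n_classes, n_per_class, size = 28, noise = 0,
                           seed = NULL) {
  if (size < 8) abort("size must be >= 8")
  fams <- toy_shape_families(size)
  if (n_classes > length(fams)) {
    abort(sprintf("at most %d shape families available, %d classes requested",
                  length(fams), n_classes))
  }
  with_local_seed(seed, {
    rows <- purrr::map(seq_len(n_classes), function(ci) {
      base <- 255 * fams[[ci]]()
      imgs <- purrr::map(seq_len(n_per_class), function(i) {
        img <- base
        if (noise > 0) {
          img <- img + matrix(rnorm(size^2, sd = noise), size, size)
        }
        pmin(pmax(img, 0), 255)
      })
      tibble::tibble(class = names(fams)[ci],
                     instance = seq_len(n_per_class), image = imgs)
    })
    dplyr::bind_rows(rows)
  })
}

#' Generate band-limited Gaussian noise
#'
#' White Gaussian noise filtered with a zero-phase 4th-order Butterworth
#' band-pass, giving a non-stationary-looking series whose power is
#' confined to `band`.  Used to build synthetic signal classes with
#' disjoint dominant bands for testing the EEG feature pathway.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param band length-2 pass band in Hz, inside `(0, fs/2)`.
#' @param seed optional seed.
#' @return numeric vector of length `n`.
#' @export
gen_band_signal <- function(n, fs, band, seed = NULL) {
  if (length(band) != 2L || band[1L] <= 0 || band[2L] >= fs / 2 ||
      band[1L] >= band[2L]) {
    abort("band must be increasing limits inside (0, fs/2)")
  }
  bw <- signal::butter(4, band / (fs / 2), type = "pass")
  with_local_seed(seed, {
    x <- rnorm(n + 2 * fs)          # pad to drop filter edge effects
    y <- signal::filtfilt(bw, x)
    y[fs + seq_len(n)]
  })
}
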