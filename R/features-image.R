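# run code with a local, restorable RNG state so generators are pure
# functions of their seed and never disturb the caller's stream
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# rotate an intensity matrix about its centre by `angle` degrees,
# inverse mapping with bilinear interpolation and zero fill
rotate_bilinear <- function(m, angle) {
  h <- nrow(m); w <- ncol(m)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(rep(seq_len(w), each = h), h, w) - cx
  # source coordinates: rotate backwards
  sy <- cy + yy * cos(th) - xx * sin(th)
  sx <- cx + yy * sin(th) + xx * cos(th)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  pick <- function(yi, xi) {
    ok <- yi >= 1 & yi <= h & xi >= 1 & xi <= w
    v <- matrix(0, h, w)
    v[ok] <- m[cbind(yi[ok], xi[ok])]
    v
  }
  pick(y0, x0) * (1 - fy) * (1 - fx) +
    pick(y0 + 1L, x0) * fy * (1 - fx) +
    pick(y0, x0 + 1L) * (1 - fy) * fx +
    pick(y0 + 1L, x0 + 1L) * fy * fx
}

# row-major flattening; colour planes concatenated
flatten_image <- function(img) {
  if (is.matrix(img)) return(as.vector(t(img)))
  if (length(dim(img)) == 3L) {
    return(as.vector(apply(img, 3L, function(p) as.vector(t(p)))))
  }
  abort("image must be a matrix or a height x width x planes array")
}

#' Build a query set from a single image
#'
#' Flattens the image row-major into one feature vector (planes
#' concatenated for colour images: 784 dimensions for 28 x 28
#' grayscale, 3072 for 32 x 32 RGB) and appends rotation-augmented
#' copies, each rotated about the image centre by an angle drawn
#' uniformly from `[-max_rotation, +max_rotation]` degrees with bilinear
#' interpolation and zero fill.  One augmented copy is normally enough
#' to give the matching phase a second query instance.
#'
#' @param img numeric matrix (grayscale) or height x width x planes
#'   array (colour); finite intensities.
#' @param copies number of augmented copies (default 1; 0 disables
#'   augmentation).
#' @param max_rotation maximum rotation magnitude in degrees (default 5).
#' @param seed optional seed making the augmentation reproducible.
#' @return tibble with `R = 1 + copies` rows and `f1..fL` columns; the
#'   original image is row 1.
#' @export
image_query_set <- function(img, copies = 1, max_rotation = 5,
                            seed = NULL) {
  if (length(img) == 0L) abort("image is empty")
  if (!all(is.finite(img))) abort("image contains non-finite intensities")
  copies <- as.integer(copies)
  if (copies < 0L) abort("copies must be >= 0")
  if (max_rotation < 0) abort("max_rotation must be >= 0")
  rows <- list(flatten_image(img))
  if (copies > 0L) {
    angles <- with_local_seed(seed,
                              runif(copies, -max_rotation, max_rotation))
    planes <- if (is.matrix(img)) list(img)
              else lapply(seq_len(dim(img)[3L]), function(p) img[, , p])
    for (a in angles) {
      rot <- lapply(planes, rotate_bilinear, angle = a)
      rows <- c(rows, list(unlist(lapply(rot, function(m) as.vector(t(m))))))
    }
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- feature_names(ncol(mat))
  tibble::as_tibble(as.data.frame(mat))
}
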