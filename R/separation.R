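#' Element-wise between-class separation scores
#'
#' For every training value `T[n, i, l]` (class n, instance i, feature
#' dimension l) the distance to the corresponding dimension of every
#' instance of every *other* class is measured with the element metric
#' (default absolute difference), averaged within each other class m to
#' give `dbar[n, i, l, m]`, and the per-class means are combined into a
#' single separation score `D[n, i, l]` (uniform mean over the N-1 other
#' classes by default; see [iatr_config()]).  Large scores mark feature
#' elements that separate their class well; the training phase retains
#' them.
#'
#' @param data data frame with a label column and numeric feature columns.
#' @param config an [iatr_config()].
#' @param class_col name of the label column.
#' @param pairwise if `TRUE`, return the per-other-class means
#'   `dbar` (long, one row per class/instance/dimension/other-class)
#'   instead of the aggregate score.
#' @return a tibble with columns `class`, `instance`, `dimension` and
#'   `score` (aggregate), or `class`, `instance`, `dimension`,
#'   `other_class`, `dist` when `pairwise = TRUE`.  All values are
#'   non-negative.
#' @examples
#' d <- tibble::tibble(class = c("a", "a", "a", "b", "b"),
#'                     f1 = c(0, 1, 4, 10, 12))
#' iatr_separation(d)
#' @export
iatr_separation <- function(data, config = iatr_config(),
                            class_col = "class", pairwise = FALSE) {
  mats <- split_classes(data, class_col)
  if (length(mats) < 2L) {
    abort("between-class separation undefined: need at least 2 classes")
  }
  if (pairwise) {
    pw <- pairwise_class_means(mats, config)
    return(dplyr::bind_rows(purrr::imap(pw, function(per_m, cl) {
      dplyr::bind_rows(purrr::imap(per_m, function(dbar, other) {
        long_scores(dbar, cl, value_name = "dist",
                    extra = list(other_class = other))
      }))
    })))
  }
  D <- separation_scores(mats, config)
  dplyr::bind_rows(purrr::imap(D, long_scores))
}

# per class n: list over other classes m of I(n) x L matrices dbar^m
pairwise_class_means <- function(mats, config) {
  dist <- metric_fun(config)
  purrr::imap(mats, function(Tn, n) {
    others <- mats[setdiff(names(mats), n)]
    lapply(others, function(Tm) {
      dbar <- matrix(0, nrow(Tn), ncol(Tn))
      for (l in seq_len(ncol(Tn))) {
        # sum-then-divide keeps ties bit-identical across code paths
        dbar[, l] <- rowSums(outer(Tn[, l], Tm[, l], dist)) / nrow(Tm)
      }
      dbar
    })
  })
}

# aggregate D[n, i, l]: named list of I(n) x L matrices.  The mean over
# the other classes is a single extended-precision sum divided once, so
# results do not depend on class iteration order.
separation_scores <- function(mats, config) {
  pw <- pairwise_class_means(mats, config)
  sizes <- vapply(mats, nrow, integer(1))
  purrr::imap(pw, function(per_m, n) {
    if (config$other_class_agg == "pooled") {
      w <- sizes[names(per_m)]
      Reduce(`+`, Map(`*`, per_m, w)) / sum(w)
    } else if (length(per_m) == 1L) {
      per_m[[1L]]
    } else {
      d1 <- dim(per_m[[1L]])
      rowSums(array(unlist(per_m), c(d1, length(per_m))), dims = 2L) /
        length(per_m)
    }
  })
}

long_scores <- function(m, cl, value_name = "score", extra = NULL) {
  out <- tibble::tibble(
    class = cl,
    instance = rep(seq_len(nrow(m)), times = ncol(m)),
    dimension = rep(seq_len(ncol(m)), each = nrow(m)))
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out[[value_name]] <- as.vector(m)
  out
}
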