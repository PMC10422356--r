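#' Configuration for the adaptive template reconstruction classifier
#'
#' Bundles the tunable parameters of both phases.  The retained template
#' count K may be given explicitly or as a fraction `P` of each class's
#' instance count (`K_n = round(P * I(n))`); the default `P = 2/3`
#' reflects the empirical finding that retaining roughly two thirds of
#' the reconstructed instances gives the best recognition rates on EEG
#' person-recognition data.  `F` is the number of finally preserved
#' template instances per class in the matching phase and `S` the number
#' of reconstructed query vectors per class (default `S = F`); both are
#' clamped to what the data allow (`F <= K`, `S <= R`) at run time.
#'
#' All sorts are stable: tied scores preserve ascending original instance
#' index.  A majority-vote tie is broken in favour of the class with the
#' smallest distance score.
#'
#' @param K integer, explicit per-class intermediate template count, or
#'   `NULL` to derive it from `P`.
#' @param P fraction in (0, 1] of each class's instances retained as
#'   intermediate templates when `K` is `NULL`.  Default 2/3.
#' @param n_final number of finally preserved template instances per
#'   class (the parameter F).  Default 4.
#' @param n_query number of reconstructed query vectors per class (the
#'   parameter S); `NULL` (default) means `S = F`.
#' @param metric element-wise distance, either the string `"l1"`
#'   (absolute difference, the default) or a vectorized function of two
#'   numeric arguments returning non-negative distances.
#' @param other_class_agg how per-other-class mean distances are combined
#'   into one separation score: `"mean"` (uniform mean over the N-1 other
#'   classes, default) or `"pooled"` (mean over all other-class
#'   instances, weighting classes by size).
#' @return an object of class `iatr_config`.
#' @examples
#' iatr_config()                 # defaults: P = 2/3, F = S = 4
#' iatr_config(K = 160)          # explicit K as used at I = 240
#' @export
iatr_config <- function(K = NULL, P = 2 / 3, n_final = 4, n_query = NULL,
                        metric = "l1",
                        other_class_agg = c("mean", "pooled")) {
  if (!is.null(K)) {
    K <- as.integer(K)
    if (length(K) != 1L || is.na(K) || K < 1L) {
      abort("K must be a single integer >= 1")
    }
  }
  if (!is.numeric(P) || length(P) != 1L || P <= 0 || P > 1) {
    abort("P must be a single value in (0, 1]")
  }
  n_final <- as.integer(n_final)
  if (length(n_final) != 1L || is.na(n_final) || n_final < 1L) {
    abort("n_final (F) must be a single integer >= 1")
  }
  if (!is.null(n_query)) {
    n_query <- as.integer(n_query)
    if (length(n_query) != 1L || is.na(n_query) || n_query < 1L) {
      abort("n_query (S) must be a single integer >= 1")
    }
  }
  if (is.character(metric)) {
    metric <- match.arg(metric, "l1")
  } else if (!is.function(metric)) {
    abort("metric must be \"l1\" or a function(x, y)")
  }
  structure(
    list(K = K, P = P, n_final = n_final, n_query = n_query,
         metric = metric,
         other_class_agg = match.arg(other_class_agg)),
    class = "iatr_config")
}

#' @export
print.iatr_config <- function(x, ...) {
  k <- if (is.null(x$K)) sprintf("round(P * I(n)) with P = %.4g", x$P)
       else as.character(x$K)
  cat("<iatr_config>\n",
      "  K (intermediate templates): ", k, "\n",
      "  F (final templates):        ", x$n_final, "\n",
      "  S (reconstructed queries):  ",
      if (is.null(x$n_query)) "F" else x$n_query, "\n",
      "  element metric:             ",
      if (is.function(x$metric)) "<function>" else x$metric, "\n",
      "  other-class aggregation:    ", x$other_class_agg, "\n", sep = "")
  invisible(x)
}

metric_fun <- function(config) {
  if (is.function(config$metric)) config$metric
  else function(x, y) abs(x - y)
}

# K_n per class: explicit K (clamped to I(n) with a warning) or round(P*I(n))
resolve_k <- function(config, sizes) {
  if (!is.null(config$K)) {
    k <- rep(config$K, length(sizes))
    if (any(k > sizes)) {
      warn(sprintf("K = %d exceeds the instance count of class(es) %s; clamped",
                   config$K,
                   paste(names(sizes)[k > sizes], collapse = ", ")))
      k <- pmin(k, sizes)
    }
  } else {
    k <- pmax(1L, pmin(sizes, as.integer(round(config$P * sizes))))
  }
  setNames(as.integer(k), names(sizes))
}
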