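#' Matching phase: query-conditioned reconstruction
#'
#' Given intermediate templates and the query vectors from one
#' observation event, re-selects — independently for every class and
#' every feature dimension — the `F` template elements and the `S` query
#' elements with the smallest mean mutual distance.  For dimension l of
#' class n the element distance `e[k, r] = dist(T'[n, k, l], Q[r, l])`
#' is computed for all template/query pairs; templates are ranked by
#' their mean distance over the R queries and queries by their mean
#' distance over the K templates (stable ties).  The retained values
#' form the final templates `T''` (F x L per class) and the
#' reconstructed queries `Q'` (S x L per class).
#'
#' `F` is clamped to each class's template count and `S` to the number
#' of available query instances R.
#'
#' @param templates an [iatr_train()] result.
#' @param query query instances from one observation event: numeric
#'   vector (single instance), R x L matrix, or data frame of numeric
#'   columns.
#' @param n_final,n_query optional overrides of the configured F and S.
#' @return an object of class `iatr_match`: list with `final` and
#'   `queries` (named lists of per-class matrices), the resolved
#'   `n_final`/`n_query`, and the config.
#' @examples
#' d <- tibble::tibble(class = c("a", "a", "a", "b", "b"),
#'                     f1 = c(0, 1, 4, 10, 12))
#' tm <- iatr_train(d, iatr_config(K = 2, n_final = 1))
#' iatr_match(tm, 3)$final
#' @export
iatr_match <- function(templates, query, n_final = NULL, n_query = NULL) {
  stopifnot(inherits(templates, "iatr_templates"))
  config <- templates$config
  L <- ncol(templates$templates[[1L]])
  Q <- as_query_matrix(query, L)
  R <- nrow(Q)
  dist <- metric_fun(config)
  n_final <- as.integer(n_final %||% config$n_final)
  n_query <- as.integer(n_query %||% config$n_query %||% n_final)
  if (n_final < 1L || n_query < 1L) abort("F and S must be >= 1")
  S <- min(n_query, R)
  final <- vector("list", length(templates$templates))
  qrec <- vector("list", length(templates$templates))
  names(final) <- names(qrec) <- names(templates$templates)
  for (n in names(templates$templates)) {
    Tp <- templates$templates[[n]]
    K <- nrow(Tp)
    F_n <- min(n_final, K)
    Tf <- matrix(0, F_n, L)
    Qr <- matrix(0, S, L)
    for (l in seq_len(L)) {
      e <- outer(Tp[, l], Q[, l], dist)        # K x R
      a <- rowSums(e) / ncol(e)                # rank key per template
      b <- colSums(e) / nrow(e)                # rank key per query
      Tf[, l] <- Tp[order_asc(a)[seq_len(F_n)], l]
      Qr[, l] <- Q[order_asc(b)[seq_len(S)], l]
    }
    colnames(Tf) <- colnames(Qr) <- colnames(Tp)
    final[[n]] <- Tf
    qrec[[n]] <- Qr
  }
  structure(
    list(final = final, queries = qrec,
         n_final = n_final, n_query = S,
         feature_names = templates$feature_names,
         config = config),
    class = "iatr_match")
}

#' @export
print.iatr_match <- function(x, ...) {
  cat("<iatr_match>\n")
  cat(sprintf("  %d classes, F = %d, S = %d\n",
              length(x$final), x$n_final, x$n_query))
  invisible(x)
}
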