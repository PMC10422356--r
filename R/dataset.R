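#' Validate and split a class-labelled feature table
#'
#' The package's working representation of a training set is a data frame
#' with one label column and L numeric feature columns, one row per
#' instance.  Classes may be unbalanced.  `split_classes()` checks the
#' invariants (at least one instance per class, identical dimensionality,
#' all values finite) and returns a named list of per-class numeric
#' matrices in order of first appearance of each label.
#'
#' @param data data frame with a label column and numeric feature columns.
#' @param class_col name of the label column (default `"class"`).
#' @return named list of I(n) x L numeric matrices, one per class, with
#'   feature names as column names.
#' @keywords internal
#' @noRd
split_classes <- function(data, class_col = "class") {
  data <- as.data.frame(data)
  if (!class_col %in% names(data)) {
    abort(sprintf("column '%s' not found in training data", class_col))
  }
  if (nrow(data) == 0L) {
    abort("training data must contain at least one instance")
  }
  labels <- as.character(data[[class_col]])
  if (anyNA(labels) || any(!nzchar(labels))) {
    abort("class labels must be non-missing and non-empty")
  }
  feat <- data[setdiff(names(data), class_col)]
  if (ncol(feat) < 1L) abort("no feature columns found")
  if (!all(vapply(feat, is.numeric, logical(1)))) {
    bad <- names(feat)[!vapply(feat, is.numeric, logical(1))]
    abort(sprintf("non-numeric feature column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  mat <- as.matrix(feat)
  if (!all(is.finite(mat))) {
    ij <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "non-finite feature value at row %d (class '%s'), dimension %d",
      ij[1L], labels[ij[1L]], ij[2L]))
  }
  classes <- unique(labels)
  out <- lapply(classes, function(cl) {
    m <- mat[labels == cl, , drop = FALSE]
    rownames(m) <- NULL
    m
  })
  names(out) <- classes
  out
}

# Queries are unlabelled: accept a bare numeric vector (one instance), a
# matrix, or a data frame of numeric columns; returns an R x L matrix.
as_query_matrix <- function(query, L = NULL) {
  if (is.data.frame(query)) {
    if ("class" %in% names(query)) query <- query[setdiff(names(query), "class")]
    query <- as.matrix(query)
  } else if (is.numeric(query) && is.null(dim(query))) {
    query <- matrix(query, nrow = 1L)
  }
  if (!is.matrix(query) || !is.numeric(query)) {
    abort("query must be a numeric vector, matrix or data frame")
  }
  if (nrow(query) < 1L) abort("query must contain at least one instance")
  if (!all(is.finite(query))) abort("query contains non-finite values")
  if (!is.null(L) && ncol(query) != L) {
    abort(sprintf("query dimensionality (%d) does not match templates (%d)",
                  ncol(query), L))
  }
  rownames(query) <- NULL
  query
}

feature_names <- function(L) sprintf("f%d", seq_len(L))

# stable sort orders: ties keep ascending original index
order_desc <- function(x) order(-x, seq_along(x))
order_asc  <- function(x) order(x, seq_along(x))
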