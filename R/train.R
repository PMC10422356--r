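#' Training phase: build intermediate templates
#'
#' Reconstructs each class's templates element by element.  Within every
#' class and feature dimension, instances are ranked by their
#' between-class separation score (see [iatr_separation()]) in
#' descending order — stably, so tied scores keep their original order —
#' and the top `K` values form the columns of the intermediate template
#' matrix.  Because each dimension is ranked independently, the k-th
#' template row generally mixes values from different original
#' instances; every reconstructed vector nevertheless stays inside the
#' class's per-dimension bounding box.
#'
#' @inheritParams iatr_separation
#' @return an object of class `iatr_templates`: a list with
#'   `templates` (named list of K_n x L matrices), `provenance` (same
#'   shape, original instance index of every element), `bounds`
#'   (per-class 2 x L min/max of the training data), `sizes`, `config`
#'   and `feature_names`.
#' @examples
#' d <- tibble::tibble(class = c("a", "a", "a", "b", "b"),
#'                     f1 = c(0, 1, 4, 10, 12))
#' tm <- iatr_train(d, iatr_config(K = 2, n_final = 1))
#' tm$templates
#' @export
iatr_train <- function(data, config = iatr_config(), class_col = "class") {
  mats <- split_classes(data, class_col)
  if (length(mats) < 2L) {
    abort("between-class separation undefined: need at least 2 classes")
  }
  D <- separation_scores(mats, config)
  sizes <- vapply(mats, nrow, integer(1))
  k_n <- resolve_k(config, sizes)
  templates <- vector("list", length(mats))
  provenance <- vector("list", length(mats))
  names(templates) <- names(provenance) <- names(mats)
  for (n in names(mats)) {
    Tn <- mats[[n]]
    L <- ncol(Tn)
    K <- k_n[[n]]
    tmpl <- matrix(0, K, L)
    prov <- matrix(0L, K, L)
    for (l in seq_len(L)) {
      idx <- order_desc(D[[n]][, l])[seq_len(K)]
      tmpl[, l] <- Tn[idx, l]
      prov[, l] <- idx
    }
    colnames(tmpl) <- colnames(Tn)
    templates[[n]] <- tmpl
    provenance[[n]] <- prov
  }
  structure(
    list(templates = templates,
         provenance = provenance,
         bounds = lapply(mats, function(m) apply(m, 2L, range)),
         sizes = sizes,
         K = k_n,
         feature_names = colnames(mats[[1L]]),
         config = config),
    class = "iatr_templates")
}

#' @export
print.iatr_templates <- function(x, ...) {
  cat("<iatr_templates>\n")
  cat(sprintf("  %d classes, %d feature dimensions\n",
              length(x$templates), ncol(x$templates[[1L]])))
  cat("  intermediate templates per class (K): ",
      paste(sprintf("%s=%d", names(x$K), x$K), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Tidy intermediate templates into a long tibble
#'
#' One row per class, template index and feature dimension, with the
#' reconstructed value and the original instance it was drawn from.
#'
#' @param x an `iatr_templates` object.
#' @param ... unused.
#' @method tidy iatr_templates
#' @export
tidy.iatr_templates <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$templates, function(m, cl) {
    out <- long_scores(m, cl, value_name = "value")
    out$source_instance <- as.vector(x$provenance[[cl]])
    names(out)[names(out) == "instance"] <- "template"
    out
  }))
}
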