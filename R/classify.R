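#' Classification stage: nearest-template majority vote
#'
#' Pools the reconstructed query vectors of all classes (S per class)
#' and assigns each pooled vector to the class of its nearest final
#' template, where the query-to-class distance is the minimum over that
#' class's F final templates of the L1 vector distance.  The decision is
#' the majority class of the assignments; a vote tie is broken in favour
#' of the class with the smallest observed query-to-template distance.
#'
#' @param match an [iatr_match()] result.
#' @return an object of class `iatr_result`: list with `decision`,
#'   `tie_broken`, `assignments` (tibble: the class each pooled vector
#'   was reconstructed for, its index, the assigned class and its
#'   distance) and `votes` (tibble: per-class vote count, vote fraction
#'   and minimum observed distance `score`).
#' @export
iatr_classify <- function(match) {
  stopifnot(inherits(match, "iatr_match"))
  classes <- names(match$final)
  pooled <- do.call(rbind, match$queries)
  if (is.null(pooled) || nrow(pooled) == 0L) {
    abort("no reconstructed query vectors to classify")
  }
  src <- rep(classes, times = vapply(match$queries, nrow, integer(1)))
  # distance of every pooled vector to every class
  dmat <- vapply(classes, function(n) {
    Tf <- match$final[[n]]
    apply(pooled, 1L, function(q) {
      min(rowSums(abs(sweep(Tf, 2L, q))))
    })
  }, numeric(nrow(pooled)))
  dmat <- matrix(dmat, nrow = nrow(pooled),
                 dimnames = list(NULL, classes))
  assigned <- apply(dmat, 1L, which.min)   # ties -> lower class index
  votes <- vapply(seq_along(classes), function(j) sum(assigned == j),
                  integer(1))
  class_scores <- apply(dmat, 2L, min)
  top <- which(votes == max(votes))
  tie_broken <- length(top) > 1L
  winner <- top[which.min(class_scores[top])]
  nearest_dist <- dmat[cbind(seq_len(nrow(pooled)), assigned)]
  structure(
    list(decision = classes[winner],
         tie_broken = tie_broken,
         assignments = tibble::tibble(
           source_class = src,
           query = seq_len(nrow(pooled)),
           assigned = classes[assigned],
           distance = nearest_dist),
         votes = tibble::tibble(
           class = classes,
           votes = votes,
           vote_fraction = votes / sum(votes),
           score = unname(class_scores))),
    class = "iatr_result")
}

#' @export
print.iatr_result <- function(x, ...) {
  cat("<iatr_result> decision:", x$decision,
      if (x$tie_broken) "(vote tie broken by distance)" else "", "\n")
  print(x$votes)
  invisible(x)
}

#' Per-class vote and score summary of a classification
#'
#' @param x an `iatr_result`.
#' @param ... unused.
#' @return tibble with one row per enrolled class: `class`, `votes`,
#'   `vote_fraction`, `score` (minimum query-to-template distance).
#' @method tidy iatr_result
#' @export
tidy.iatr_result <- function(x, ...) x$votes

#' One-row summary of a classification
#'
#' @param x an `iatr_result`.
#' @param ... unused.
#' @method glance iatr_result
#' @export
glance.iatr_result <- function(x, ...) {
  tibble::tibble(
    decision = x$decision,
    vote_fraction = x$votes$vote_fraction[x$votes$class == x$decision],
    score = x$votes$score[x$votes$class == x$decision],
    tie_broken = x$tie_broken)
}

#' End-to-end adaptive template reconstruction prediction
#'
#' Composes the training phase, matching phase and classification stage
#' with one configuration: [iatr_train()] then [iatr_match()] then
#' [iatr_classify()].  Deterministic for fixed inputs.
#'
#' @inheritParams iatr_separation
#' @param query query instances from one observation event (vector,
#'   matrix or data frame).
#' @return an `iatr_result` (see [iatr_classify()]).
#' @examples
#' d <- tibble::tibble(class = rep(c("a", "b"), c(3, 2)),
#'                     f1 = c(0, 1, 4, 10, 12))
#' res <- iatr_predict(d, 3, iatr_config(K = 2, n_final = 1))
#' res$decision
#' @export
iatr_predict <- function(data, query, config = iatr_config(),
                         class_col = "class") {
  tm <- iatr_train(data, config, class_col)
  iatr_classify(iatr_match(tm, query))
}

#' Predict method for fitted templates
#'
#' @param object an `iatr_templates` object.
#' @param query query instances from one observation event.
#' @param ... unused.
#' @return an `iatr_result`.
#' @export
predict.iatr_templates <- function(object, query, ...) {
  iatr_classify(iatr_match(object, query))
}

#' Per-class verification (distance) scores
#'
#' For verification each enrolled class n is scored against its *own*
#' reconstructed query set: `score(n)` is the minimum over the class's S
#' reconstructed query vectors of the minimum L1 distance to the class's
#' F final templates.  Lower scores mean greater similarity; a genuine
#' comparison scores the claimed class, an impostor comparison a
#' different one.  These distances feed the DET/EER analysis
#' ([det_eer()]).
#'
#' @param x either an [iatr_match()] result, or a training data frame
#'   (in which case `query` and `config` are used to run the training
#'   and matching phases first).
#' @param query,config,class_col used only when `x` is a data frame.
#' @return tibble with columns `class` and `score` (non-negative).
#' @export
iatr_verification_scores <- function(x, query = NULL,
                                     config = iatr_config(),
                                     class_col = "class") {
  if (!inherits(x, "iatr_match")) {
    tm <- iatr_train(x, config, class_col)
    x <- iatr_match(tm, query)
  }
  scores <- vapply(names(x$final), function(n) {
    Tf <- x$final[[n]]
    Qr <- x$queries[[n]]
    min(apply(Qr, 1L, function(q) min(rowSums(abs(sweep(Tf, 2L, q))))))
  }, numeric(1))
  tibble::tibble(class = names(x$final), score = unname(scores))
}
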