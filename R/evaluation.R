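#' Cumulative match characteristic (CMC) curve
#'
#' Rank-k identification accuracy: the fraction of query events whose
#' true class is among the k best (smallest) scores.  Tied scores are
#' resolved pessimistically — the true class's rank counts every class
#' scoring less than or equal to it — so the curve is deterministic and
#' conservative.
#'
#' @param scores numeric matrix or data frame, one row per query event
#'   and one column per enrolled class (column names are the class
#'   labels); lower = better.
#' @param truth vector of true class labels, one per event.
#' @return a tibble of class `iatr_cmc` with columns `rank` (1..N) and
#'   `accuracy`, monotone non-decreasing with `accuracy[N] == 1`.
#' @examples
#' s <- rbind(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
#' colnames(s) <- c("a", "b", "c")
#' cmc(s, c("a", "c", "a"))
#' @export
cmc <- function(scores, truth) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L) abort("empty score table")
  if (is.null(colnames(scores))) abort("score columns must be named by class")
  if (!all(is.finite(scores))) abort("scores must be finite")
  truth <- as.character(truth)
  if (length(truth) != nrow(scores)) abort("one true label per event required")
  if (!all(truth %in% colnames(scores))) {
    abort("every true label must be an enrolled class")
  }
  n <- ncol(scores)
  s_true <- scores[cbind(seq_len(nrow(scores)), match(truth, colnames(scores)))]
  event_rank <- rowSums(scores <= s_true)   # worst-case rank under ties
  acc <- vapply(seq_len(n), function(k) mean(event_rank <= k), numeric(1))
  out <- tibble::tibble(rank = seq_len(n), accuracy = acc)
  class(out) <- c("iatr_cmc", class(out))
  out
}

#' Detection error trade-off curve and equal error rate
#'
#' Sweeps an acceptance threshold over the pooled support of the
#' genuine and impostor distance scores (lower = more similar = accept).
#' At threshold t the false acceptance rate is the fraction of impostor
#' scores `<= t` and the false rejection rate the fraction of genuine
#' scores `> t`.  The equal error rate is the midpoint of the two rates
#' at the threshold minimizing their absolute difference, in percent.
#'
#' @param genuine numeric vector of genuine-comparison scores.
#' @param impostor numeric vector of impostor-comparison scores.
#' @return an object of class `iatr_det`: list with `sweep` (tibble:
#'   `threshold`, `far`, `frr`) and `eer` (percent, in `[0, 50]`).
#' @examples
#' det_eer(c(1, 2, 9), c(3, 8, 10))$eer   # 33.33
#' @export
det_eer <- function(genuine, impostor) {
  if (length(genuine) == 0L || length(impostor) == 0L) {
    abort("genuine and impostor score lists must both be nonempty")
  }
  if (!all(is.finite(c(genuine, impostor)))) abort("scores must be finite")
  thr <- sort(unique(c(genuine, impostor)))
  thr <- c(min(thr) - 1, thr)          # include an accept-nothing point
  far <- vapply(thr, function(t) mean(impostor <= t), numeric(1))
  frr <- vapply(thr, function(t) mean(genuine > t), numeric(1))
  i <- which.min(abs(far - frr))
  structure(
    list(sweep = tibble::tibble(threshold = thr, far = far, frr = frr),
         eer = 100 * (far[i] + frr[i]) / 2),
    class = "iatr_det")
}

#' @export
print.iatr_det <- function(x, ...) {
  cat(sprintf("<iatr_det> EER = %.2f%% over %d thresholds\n",
              x$eer, nrow(x$sweep)))
  invisible(x)
}

#' @method glance iatr_det
#' @export
glance.iatr_det <- function(x, ...) tibble::tibble(eer = x$eer)

#' @method tidy iatr_det
#' @export
tidy.iatr_det <- function(x, ...) x$sweep

#' Nearest-neighbour baseline classifier
#'
#' Each query row votes for the class of its nearest training row
#' (Euclidean distance by default); the prediction is the majority
#' vote, with ties broken in favour of the class appearing first in the
#' training table.
#'
#' @inheritParams iatr_separation
#' @param query query instances (vector, matrix or data frame).
#' @param metric `"euclidean"` (default) or `"l1"` row distance.
#' @return the predicted class label (length-1 character).
#' @export
nn_baseline <- function(data, query, class_col = "class",
                        metric = c("euclidean", "l1")) {
  metric <- match.arg(metric)
  mats <- split_classes(data, class_col)
  classes <- names(mats)
  train <- do.call(rbind, mats)
  labels <- rep(classes, vapply(mats, nrow, integer(1)))
  Q <- as_query_matrix(query, ncol(train))
  votes <- integer(length(classes))
  names(votes) <- classes
  for (r in seq_len(nrow(Q))) {
    d <- if (metric == "euclidean") {
      sqrt(rowSums(sweep(train, 2L, Q[r, ])^2))
    } else {
      rowSums(abs(sweep(train, 2L, Q[r, ])))
    }
    cl <- labels[which.min(d)]
    votes[cl] <- votes[cl] + 1L
  }
  classes[which.max(votes)]            # ties -> first enrolled class
}

#' Run an identification experiment
#'
#' Classifies a set of query events with the full two-phase pipeline
#' and summarizes identification performance.  Either supply explicit
#' `queries` (each a query set plus its true class), or a `folds`
#' count, in which case each class's instances are partitioned into
#' `folds` contiguous blocks (recordings), each block is held out in
#' turn as the query event while the rest trains the system, and
#' results are pooled over rotations (leave-one-recording-out
#' cross-validation).
#'
#' @inheritParams iatr_separation
#' @param queries list of query events, each a list with elements
#'   `query` (vector/matrix/data frame) and `class` (true label).
#'   Ignored when `folds` is given.
#' @param folds optional number of recordings per class for
#'   leave-one-out rotation.
#' @return an object of class `iatr_ident`: list with `accuracy`,
#'   `confusion` (N x N matrix, rows = truth), and `score_table`
#'   (tibble: `event`, `truth`, `class`, `score`) suitable for [cmc()]
#'   and [det_eer()].
#' @export
identification_experiment <- function(data, queries = NULL,
                                      config = iatr_config(),
                                      class_col = "class", folds = NULL) {
  mats <- split_classes(data, class_col)
  if (length(mats) < 2L) abort("need at least 2 enrolled classes")
  classes <- names(mats)
  if (!is.null(folds)) {
    folds <- as.integer(folds)
    if (folds < 2L) abort("folds must be >= 2")
    feats <- setdiff(names(data), class_col)
    runs <- lapply(seq_len(folds), function(f) {
      train_rows <- list(); query_events <- list()
      for (cl in classes) {
        m <- mats[[cl]]
        blk <- cut(seq_len(nrow(m)), folds, labels = FALSE)
        train_rows[[cl]] <- m[blk != f, , drop = FALSE]
        query_events[[cl]] <- list(query = m[blk == f, , drop = FALSE],
                                   class = cl)
      }
      train <- dplyr::bind_rows(purrr::imap(train_rows, function(m, cl) {
        dplyr::bind_cols(tibble::tibble(class = cl),
                         tibble::as_tibble(as.data.frame(m)))
      }))
      names(train)[1L] <- class_col
      identification_experiment(train, unname(query_events), config,
                                class_col = class_col)
    })
    conf <- Reduce(`+`, lapply(runs, `[[`, "confusion"))
    st <- dplyr::bind_rows(purrr::imap(runs, function(r, i) {
      dplyr::mutate(r$score_table,
                    event = .data$event + (i - 1L) * length(classes))
    }))
    out <- list(accuracy = mean(vapply(runs, `[[`, numeric(1), "accuracy")),
                confusion = conf, score_table = st)
    class(out) <- "iatr_ident"
    return(out)
  }
  if (is.null(queries) || length(queries) == 0L) {
    abort("supply either queries or folds")
  }
  tm <- iatr_train(data, config, class_col)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(truth = classes, predicted = classes))
  rows <- vector("list", length(queries))
  correct <- logical(length(queries))
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    mt <- iatr_match(tm, q$query)
    res <- iatr_classify(mt)
    sc <- iatr_verification_scores(mt)
    conf[q$class, res$decision] <- conf[q$class, res$decision] + 1L
    correct[i] <- identical(res$decision, as.character(q$class))
    rows[[i]] <- tibble::tibble(event = i, truth = as.character(q$class),
                                class = sc$class, score = sc$score)
  }
  out <- list(accuracy = mean(correct), confusion = conf,
              score_table = dplyr::bind_rows(rows))
  class(out) <- "iatr_ident"
  out
}

#' @export
print.iatr_ident <- function(x, ...) {
  cat(sprintf("<iatr_ident> accuracy = %.3f over %d events\n",
              x$accuracy, length(unique(x$score_table$event))))
  invisible(x)
}

#' @method glance iatr_ident
#' @export
glance.iatr_ident <- function(x, ...) {
  wide <- score_table_wide(x$score_table)
  cm <- cmc(wide$scores, wide$truth)
  gi <- genuine_impostor(x$score_table)
  tibble::tibble(accuracy = x$accuracy,
                 rank1 = cm$accuracy[1L],
                 eer = det_eer(gi$genuine, gi$impostor)$eer)
}

# reshape the long score table into an events x classes matrix + truth
score_table_wide <- function(score_table) {
  wide <- tidyr::pivot_wider(score_table, id_cols = c("event", "truth"),
                             names_from = "class", values_from = "score")
  scores <- as.matrix(wide[setdiff(names(wide), c("event", "truth"))])
  list(scores = scores, truth = wide$truth)
}

#' Split a score table into genuine and impostor scores
#'
#' A genuine comparison scores the event's true class; every other
#' enrolled class provides one impostor comparison per event.
#'
#' @param score_table tibble with columns `event`, `truth`, `class`,
#'   `score` (as produced by [identification_experiment()]).
#' @return list with numeric vectors `genuine` and `impostor`.
#' @export
genuine_impostor <- function(score_table) {
  gen <- score_table$score[score_table$class == score_table$truth]
  imp <- score_table$score[score_table$class != score_table$truth]
  list(genuine = gen, impostor = imp)
}
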