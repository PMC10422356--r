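#' Plot a cumulative match characteristic curve
#'
#' @param object an `iatr_cmc` tibble from [cmc()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot iatr_cmc
#' @export
autoplot.iatr_cmc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$accuracy)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Rank", y = "Identification accuracy",
                  title = "Cumulative match characteristic") +
    ggplot2::theme_minimal()
}

#' Plot a detection error trade-off curve
#'
#' False rejection against false acceptance over the threshold sweep,
#' with the equal error rate marked.
#'
#' @param object an `iatr_det` object from [det_eer()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot iatr_det
#' @export
autoplot.iatr_det <- function(object, ...) {
  eer <- object$eer / 100
  ggplot2::ggplot(object$sweep, ggplot2::aes(x = .data$far, y = .data$frr)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::annotate("point", x = eer, y = eer, colour = "red") +
    ggplot2::annotate("text", x = eer, y = eer,
                      label = sprintf(" EER = %.1f%%", object$eer),
                      hjust = 0, vjust = -0.5, size = 3) +
    ggplot2::labs(x = "False acceptance rate", y = "False rejection rate",
                  title = "Detection error trade-off") +
    ggplot2::theme_minimal()
}

#' Plot per-class vote fractions of a classification
#'
#' @param object an `iatr_result` from [iatr_classify()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot iatr_result
#' @export
autoplot.iatr_result <- function(object, ...) {
  df <- object$votes
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$vote_fraction,
                                   fill = .data$class == object$decision)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "steelblue")) +
    ggplot2::labs(x = "Class", y = "Vote fraction",
                  title = sprintf("Decision: %s", object$decision)) +
    ggplot2::theme_minimal()
}
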