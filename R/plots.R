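#' Plot an accuracy curve
#'
#' Mean cross-validated accuracy with one-standard-deviation error bars as a
#' function of model size, with the high-water mark (dashed) and, when known,
#' the selected r* (dotted vertical line).
#'
#' @param object an `accuracy_curve` or `fitted_fs_svm`.
#' @param r_star optional model size to mark.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot accuracy_curve
#' @export
autoplot.accuracy_curve <- function(object, r_star = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$mean_acc)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_acc - .data$sd_acc,
                                        ymax = .data$mean_acc + .data$sd_acc),
                           width = 0.25, color = "grey50") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::geom_hline(yintercept = max(df$mean_acc), linetype = "dashed",
                        color = "grey30") +
    ggplot2::labs(x = "number of features (r)",
                  y = "cross-validated accuracy",
                  title = "Accuracy vs model size") +
    ggplot2::theme_minimal()
  if (!is.null(r_star)) {
    p <- p + ggplot2::geom_vline(xintercept = r_star, linetype = "dotted")
  }
  p
}

#' @rdname autoplot.accuracy_curve
#' @method autoplot fitted_fs_svm
#' @export
autoplot.fitted_fs_svm <- function(object, ...) {
  autoplot(object$curve, r_star = object$r_star) +
    ggplot2::labs(subtitle = sprintf("r* = %d (one-SD rule)", object$r_star))
}

#' Plot a feature ranking
#'
#' Relevance (MI with the class, bits) and mRMR score by rank.
#'
#' @param object a `ranked_features` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot ranked_features
#' @export
autoplot.ranked_features <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("relevance", "mrmr_score"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature_id, -.data$rank),
                                   y = .data$value, fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "bits / score", title = "mRMR feature ranking") +
    ggplot2::theme_minimal()
}

#' Waterfall plot of classifier scores
#'
#' Samples sorted by decreasing score, colored by call — the standard way to
#' eyeball how well a linear rule separates a cohort and how many samples sit
#' near the decision boundary.
#'
#' @param calls output of [eq3_classify()] or [predict.linear_model()].
#' @param score,label column names to use.
#' @return A ggplot.
#' @export
plot_score_waterfall <- function(calls, score = "score",
                                 label = intersect(c("er_call", "label"), names(calls))[1]) {
  df <- dplyr::arrange(calls, dplyr::desc(.data[[score]]))
  df$ord <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ord, y = .data[[score]],
                                   fill = .data[[label]])) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = 0, color = "grey30") +
    ggplot2::labs(x = "samples (sorted by score)", y = "classifier score") +
    ggplot2::theme_minimal()
}
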