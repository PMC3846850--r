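#' Tidiers for fitted objects
#'
#' `tidy()` on a `linear_model` returns one row per term (the threshold
#' appears as term `"(threshold)"`). On a `fitted_fs_svm` it additionally
#' joins the full-data mRMR rank, relevance and score of each selected
#' feature. `glance()` on a `fitted_fs_svm` gives the one-row model summary.
#'
#' @param x a fitted object.
#' @param ... unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy linear_model
#' @export
tidy.linear_model <- function(x, ...) {
  tibble::tibble(
    term = c(x$features, "(threshold)"),
    estimate = c(unname(x$weights), x$threshold)
  )
}

#' @rdname tidiers
#' @method tidy fitted_fs_svm
#' @export
tidy.fitted_fs_svm <- function(x, ...) {
  dplyr::left_join(
    tidy(x$model),
    dplyr::rename(tibble::as_tibble(x$ranking), term = "feature_id"),
    by = "term"
  )
}

#' @rdname tidiers
#' @method glance fitted_fs_svm
#' @export
glance.fitted_fs_svm <- function(x, ...) {
  tibble::tibble(
    r_star = x$r_star,
    cv_accuracy = x$cv_accuracy[["mean"]],
    cv_sd = x$cv_accuracy[["sd"]],
    k_folds = attr(x$curve, "k"),
    r_max = nrow(x$curve)
  )
}

#' @rdname tidiers
#' @method tidy accuracy_curve
#' @export
tidy.accuracy_curve <- function(x, ...) tibble::as_tibble(x)
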