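#' Stratified cross-validation folds
#'
#' Partitions the samples of a labeled dataset into `k` balanced folds: fold
#' sizes differ by at most one, and each class's count differs by at most one
#' across folds. Construction is deal-out: within each class the sample ids
#' are shuffled by a seeded generator, then dealt round-robin into folds,
#' with the dealing position carried over between classes so overall fold
#' sizes stay balanced too.
#'
#' A minority class smaller than `k` is allowed (some folds then carry none of
#' it, still within the one-per-fold balance bound), but each class needs at
#' least two members so that every training complement sees both classes.
#'
#' @param d a `labeled_dataset`.
#' @param k number of folds (>= 2).
#' @param seed integer seed; the same seed always yields the same partition.
#' @return List of `k` character vectors of sample ids (disjoint, covering).
#' @export
stratified_folds <- function(d, k, seed) {
  if (k < 2) abort("`k` must be >= 2.")
  counts <- table(d$labels$label)
  if (any(counts < 2)) {
    abort(paste0("Class(es) with fewer than 2 samples: ",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  folds <- vector("list", k)
  pos <- 0L
  withr::with_seed(seed, {
    for (cl in levels(d$labels$label)) {
      ids <- d$labels$sample_id[d$labels$label == cl]
      ids <- sample(ids)
      for (id in ids) {
        f <- (pos %% k) + 1L
        folds[[f]] <- c(folds[[f]], id)
        pos <- pos + 1L
      }
    }
  })
  folds
}

#' Linear soft-margin SVM on a feature subset
#'
#' Trains a maximum-margin linear separator (soft margin, regularization
#' constant `c_param`, default 1) on the listed features only, and returns it
#' as a `linear_model`: a named weight vector plus threshold, with prediction
#' depending only on the sign of `w . x + w0`. Backed by the libsvm solver
#' (via e1071); inputs are not rescaled, so apply [zscore()] first.
#'
#' @param d a `labeled_dataset`.
#' @param feature_subset features to use (must exist in `d`).
#' @param c_param soft-margin cost C.
#' @return A `linear_model`.
#' @export
train_linear_svm <- function(d, feature_subset, c_param = 1) {
  if (length(feature_subset) == 0) abort("`feature_subset` must be non-empty.")
  missing <- setdiff(feature_subset, feature_ids(d$matrix))
  if (length(missing) > 0) {
    abort(paste0("Feature(s) not in dataset: ", paste(missing, collapse = ", ")))
  }
  if (length(unique(d$labels$label)) < 2) abort("Need samples from both classes.")
  X <- t(em_matrix(d$matrix))[, feature_subset, drop = FALSE]
  y <- factor(as.character(d$labels$label), levels = c("positive", "negative"))
  fit <- e1071::svm(X, y, kernel = "linear", cost = c_param, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  w0 <- -fit$rho
  # libsvm orients the decision function toward the class it saw first;
  # fit$labels records that order, so flip when "positive" (level 1) is not
  # the positive side
  if (fit$labels[1] != 1L) {
    w <- -w
    w0 <- -w0
  }
  new_linear_model(features = feature_subset, weights = setNames(w, feature_subset),
                   threshold = w0, training_stage = stage(d$matrix))
}

new_linear_model <- function(features, weights, threshold, training_stage) {
  stopifnot(length(weights) == length(features))
  structure(list(features = features, weights = weights, threshold = threshold,
                 training_stage = training_stage),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("# linear_model: %d feature(s), threshold %.4f, expects stage '%s'\n",
              length(x$features), x$threshold, x$training_stage))
  print(round(x$weights, 4))
  invisible(x)
}

#' Predict class labels from a linear model
#'
#' Scores are `w . x + w0`; a sample is called positive when its score is
#' `>= 0` (exact ties go to positive, by convention).
#'
#' @param object a `linear_model`.
#' @param newdata an `expr_mat`, a samples-by-features data frame/matrix, or
#'   a single named numeric vector of feature values.
#' @param ... unused.
#' @return Tibble with `sample_id`, `score`, `label`.
#' @export
predict.linear_model <- function(object, newdata, ...) {
  X <- coerce_sample_matrix(newdata, object$features)
  score <- drop(X %*% object$weights[object$features]) + object$threshold
  tibble::tibble(
    sample_id = rownames(X),
    score = unname(score),
    label = factor(ifelse(score >= 0, "positive", "negative"),
                   levels = c("negative", "positive"))
  )
}

coerce_sample_matrix <- function(newdata, features) {
  if (inherits(newdata, "expr_mat")) {
    X <- t(em_matrix(newdata))
  } else if (is.numeric(newdata) && is.null(dim(newdata))) {
    X <- matrix(newdata, nrow = 1, dimnames = list("sample_1", names(newdata)))
  } else {
    X <- as.matrix(newdata)
    if (is.null(rownames(X))) rownames(X) <- paste0("sample_", seq_len(nrow(X)))
  }
  missing <- setdiff(features, colnames(X))
  if (length(missing) > 0) {
    abort(paste0("Missing feature(s) in new data: ", paste(missing, collapse = ", ")))
  }
  X[, features, drop = FALSE]
}

#' Cross-validated accuracy as a function of model size
#'
#' For each of `k` stratified folds, features are ranked by mRMR on the
#' training portion only (the held-out fold contributes nothing to its own
#' ranking), a linear SVM is trained on the top r features for every
#' r = 1..`r_max`, and accuracy is scored on the held-out fold. Fold
#' accuracies are aggregated into a mean `mean_acc` and sample standard
#' deviation `sd_acc` (divisor k - 1) per r.
#'
#' @param d a `labeled_dataset` (typically at stage `"zscore"`).
#' @param r_max largest model size to evaluate.
#' @param k number of folds.
#' @param seed fold-construction seed.
#' @param c_param SVM cost.
#' @param pool_size mRMR candidate-pool size (see [mrmr_rank()]); default
#'   `max(3 * r_max, 40)`, capped at the feature count.
#' @param n_grid,pair_grid quadrature grids for the MI estimates.
#' @return An `accuracy_curve` tibble (`r`, `mean_acc`, `sd_acc`) with the
#'   per-fold accuracy matrix and per-fold rankings attached as attributes.
#' @export
accuracy_curve <- function(d, r_max = 18, k = 10, seed = 1, c_param = 1,
                           pool_size = max(3 * r_max, 40),
                           n_grid = 512, pair_grid = 64) {
  p <- nrow(d$matrix)
  if (r_max > p) abort("`r_max` exceeds the number of features.")
  pool_size <- min(pool_size, p)
  folds <- stratified_folds(d, k, seed)
  all_ids <- d$labels$sample_id
  acc <- matrix(NA_real_, nrow = k, ncol = r_max)
  rankings <- vector("list", k)
  for (i in seq_len(k)) {
    train <- ld_subset(d, setdiff(all_ids, folds[[i]]))
    test <- ld_subset(d, folds[[i]])
    rk <- mrmr_rank(train, top_k = r_max, pool_size = pool_size,
                    n_grid = n_grid, pair_grid = pair_grid)
    rankings[[i]] <- rk
    truth <- test$labels$label
    Xte <- t(em_matrix(test$matrix))
    for (r in seq_len(r_max)) {
      mod <- train_linear_svm(train, rk$feature_id[seq_len(r)], c_param = c_param)
      pred <- predict(mod, Xte)
      acc[i, r] <- mean(pred$label == truth)
    }
  }
  out <- tibble::tibble(
    r = seq_len(r_max),
    mean_acc = colMeans(acc),
    sd_acc = apply(acc, 2, sd)
  )
  class(out) <- c("accuracy_curve", class(out))
  attr(out, "k") <- k
  attr(out, "fold_accuracies") <- acc
  attr(out, "fold_rankings") <- rankings
  attr(out, "seed") <- seed
  out
}

#' One-standard-deviation model-size rule
#'
#' Given an accuracy curve, returns the smallest model size r whose
#' `mean + sd` reaches the high-water-mark mean accuracy:
#' `r* = min { r : a_r + sd_r >= max a }`. The maximizer itself always
#' qualifies, so r* exists and never exceeds the argmax.
#'
#' @param curve an `accuracy_curve` (or any tibble with `r`, `mean_acc`,
#'   `sd_acc`).
#' @return Integer r*.
#' @export
select_r_star <- function(curve) {
  if (nrow(curve) == 0) abort("Empty accuracy curve.")
  hwm <- max(curve$mean_acc)
  as.integer(curve$r[which(curve$mean_acc + curve$sd_acc >= hwm)[1]])
}

#' Feature-selecting SVM
#'
#' The full wrapper: (1) build the cross-validated [accuracy_curve()] with
#' per-fold mRMR rankings; (2) pick the model size r* by the
#' one-standard-deviation rule ([select_r_star()]); (3) re-rank features by
#' mRMR on the complete dataset and train the final linear SVM on the top r*
#' features. The reported `cv_accuracy` is the curve's mean and sd at r*.
#'
#' @inheritParams accuracy_curve
#' @return A `fitted_fs_svm` object: `r_star`, `ranking` (full-data
#'   `ranked_features`), `model` (`linear_model` over r* features), `curve`,
#'   and `cv_accuracy` (named mean/sd).
#' @export
fit_fs_svm <- function(d, r_max = 18, k = 10, seed = 1, c_param = 1,
                       pool_size = max(3 * r_max, 40),
                       n_grid = 512, pair_grid = 64) {
  if (stage(d$matrix) != "zscore") {
    warn(paste0("fit_fs_svm() is intended for z-scored data; got stage '",
                stage(d$matrix), "'."))
  }
  curve <- accuracy_curve(d, r_max = r_max, k = k, seed = seed, c_param = c_param,
                          pool_size = pool_size, n_grid = n_grid,
                          pair_grid = pair_grid)
  r_star <- select_r_star(curve)
  ranking <- mrmr_rank(d, top_k = r_max, pool_size = min(pool_size, nrow(d$matrix)),
                       n_grid = n_grid, pair_grid = pair_grid)
  model <- train_linear_svm(d, ranking$feature_id[seq_len(r_star)], c_param = c_param)
  structure(list(
    r_star = r_star,
    ranking = ranking,
    model = model,
    curve = curve,
    cv_accuracy = c(mean = curve$mean_acc[r_star], sd = curve$sd_acc[r_star])
  ), class = "fitted_fs_svm")
}

#' @export
print.fitted_fs_svm <- function(x, ...) {
  cat(sprintf("# fitted_fs_svm: r* = %d, CV accuracy %.2f%% +/- %.2f%% (%d folds)\n",
              x$r_star, 100 * x$cv_accuracy[["mean"]], 100 * x$cv_accuracy[["sd"]],
              attr(x$curve, "k")))
  cat("# selected features: ", paste(x$model$features, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
predict.fitted_fs_svm <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}
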