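test_that("stratified folds are balanced, covering, and deterministic", {
  v <- matrix(rnorm(20), 1, 20, dimnames = list("f1", paste0("s", 1:20)))
  lab <- rep(c("positive", "negative"), c(12, 8))
  d20 <- make_ld(v, lab)
  folds <- stratified_folds(d20, k = 10, seed = 7)
  expect_length(folds, 10)
  expect_setequal(unlist(folds), paste0("s", 1:20))
  expect_true(all(lengths(folds) == 2))
  pos_per_fold <- vapply(folds, function(f) sum(f %in% paste0("s", 1:12)), numeric(1))
  expect_true(all(pos_per_fold %in% 1:2))

  expect_identical(stratified_folds(d20, 10, seed = 7), folds)
  expect_false(identical(stratified_folds(d20, 10, seed = 8), folds))

  d1 <- make_ld(matrix(rnorm(5), 1, 5, dimnames = list("f1", paste0("s", 1:5))),
                c("positive", rep("negative", 4)))
  expect_error(stratified_folds(d1, k = 2, seed = 1), "fewer than 2")
})

test_that("a 176-sample cohort with 112 positives folds into sizes 17-18", {
  v <- matrix(rnorm(176), 1, 176, dimnames = list("f1", sprintf("s%03d", 1:176)))
  lab <- rep(c("positive", "negative"), c(112, 64))
  d <- make_ld(v, lab)
  folds <- stratified_folds(d, k = 10, seed = 42)
  expect_true(all(lengths(folds) %in% c(17, 18)))
  pos <- vapply(folds, function(f) sum(f %in% sprintf("s%03d", 1:112)), numeric(1))
  expect_true(all(pos %in% c(11, 12)))
  expect_equal(sum(lengths(folds)), 176)
  expect_equal(anyDuplicated(unlist(folds)), 0)
})

test_that("the linear SVM recovers closed-form separable solutions", {
  # symmetric pair: boundary at 0
  d <- make_ld(matrix(c(-1, 1), 1, 2, dimnames = list("f1", c("a", "b"))),
               c("negative", "positive"))
  m <- train_linear_svm(d, "f1")
  pred <- predict(m, d$matrix)
  expect_equal(as.character(pred$label), c("negative", "positive"))
  expect_lt(abs(m$threshold / m$weights[["f1"]]), 1e-6)  # boundary at x = 0

  # points at 0 and 2: maximum-margin midpoint at x = 1
  d2 <- make_ld(matrix(c(0, 2), 1, 2, dimnames = list("f1", c("a", "b"))),
                c("negative", "positive"))
  m2 <- train_linear_svm(d2, "f1")
  boundary <- -m2$threshold / m2$weights[["f1"]]
  expect_equal(boundary, 1, tolerance = 1e-6)

  # separable 2-D fixture: training accuracy 1
  withr::with_seed(11, {
    v <- rbind(x = c(rnorm(20, -2), rnorm(20, 2)),
               y = rnorm(40))
    colnames(v) <- paste0("s", 1:40)
  })
  d3 <- make_ld(v, rep(c("negative", "positive"), each = 20))
  m3 <- train_linear_svm(d3, c("x", "y"))
  expect_equal(mean(predict(m3, d3$matrix)$label == d3$labels$label), 1)

  expect_error(train_linear_svm(d3, character(0)), "non-empty")
  expect_error(train_linear_svm(d3, "nope"), "nope")
})

test_that("prediction is sign(w.x + w0) with ties going positive", {
  m <- ersvm:::new_linear_model("f1", c(f1 = 1), threshold = -1,
                                training_stage = "zscore")
  expect_equal(as.character(predict(m, c(f1 = 2))$label), "positive")
  expect_equal(as.character(predict(m, c(f1 = 0))$label), "negative")
  expect_equal(as.character(predict(m, c(f1 = 1))$label), "positive")  # tie
  expect_error(predict(m, c(f2 = 1)), "f1")
})

test_that("duplicating one training sample per class leaves separable predictions unchanged", {
  withr::with_seed(12, {
    v <- rbind(f1 = c(rnorm(10, -3), rnorm(10, 3)), f2 = rnorm(20))
    colnames(v) <- paste0("s", 1:20)
  })
  lab <- rep(c("negative", "positive"), each = 10)
  d <- make_ld(v, lab)
  m <- train_linear_svm(d, c("f1", "f2"))

  v2 <- cbind(v, s21 = v[, 1], s22 = v[, 11])
  d2 <- make_ld(v2, c(lab, "negative", "positive"))
  m2 <- train_linear_svm(d2, c("f1", "f2"))
  grid <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("q", 1:20), c("f1", "f2")))
  expect_equal(predict(m, grid)$label, predict(m2, grid)$label)
})

test_that("the one-SD rule picks the smallest size within a SD of the high-water mark", {
  curve <- tibble::tibble(r = 1:4,
                          mean_acc = c(0.80, 0.85, 0.92, 0.93),
                          sd_acc = c(0.01, 0.01, 0.02, 0.01))
  expect_equal(select_r_star(curve), 3L)  # max at r=4, but 0.92+0.02 >= 0.93

  inc <- tibble::tibble(r = 1:5, mean_acc = seq(0.5, 0.9, 0.1), sd_acc = rep(0, 5))
  expect_equal(select_r_star(inc), 5L)

  flat <- tibble::tibble(r = 1:6, mean_acc = rep(0.8, 6), sd_acc = rep(0.03, 6))
  expect_equal(select_r_star(flat), 1L)
})

test_that("r* never exceeds the argmax, with equality when sds vanish at a unique max", {
  withr::with_seed(13, {
    for (i in 1:25) {
      curve <- tibble::tibble(r = 1:10, mean_acc = runif(10, 0.5, 1),
                              sd_acc = runif(10, 0, 0.1))
      expect_lte(select_r_star(curve), which.max(curve$mean_acc))
    }
    curve0 <- tibble::tibble(r = 1:10, mean_acc = sample(seq(0.5, 0.95, 0.05)),
                             sd_acc = rep(0, 10))
    expect_equal(select_r_star(curve0), which.max(curve0$mean_acc))
  })
})

test_that("the accuracy curve has the declared shape and fold bookkeeping", {
  d <- random_ld(n = 40, p = 8, seed = 700, prior = 0.5)
  curve <- accuracy_curve(d, r_max = 3, k = 4, seed = 2)
  expect_s3_class(curve, "accuracy_curve")
  expect_equal(curve$r, 1:3)
  acc <- attr(curve, "fold_accuracies")
  expect_equal(dim(acc), c(4, 3))
  expect_equal(colMeans(acc), curve$mean_acc)
  expect_equal(apply(acc, 2, sd), curve$sd_acc)  # sd over exactly k folds
  expect_length(attr(curve, "fold_rankings"), 4)
})

test_that("per-fold rankings never use the held-out fold", {
  d <- random_ld(n = 40, p = 6, seed = 701)
  folds <- stratified_folds(d, k = 4, seed = 3)
  curve <- accuracy_curve(d, r_max = 3, k = 4, seed = 3)
  # corrupt fold 2's values wildly; fold-2 ranking must not move
  v <- em_matrix(d$matrix)
  v[, folds[[2]]] <- v[, folds[[2]]] * 100 + 1000
  d2 <- make_ld(v, as.character(d$labels$label))
  train_ids <- setdiff(d$labels$sample_id, folds[[2]])
  rk_clean <- mrmr_rank(ersvm:::ld_subset(d, train_ids), top_k = 3)
  rk_dirty <- mrmr_rank(ersvm:::ld_subset(d2, train_ids), top_k = 3)
  expect_identical(rk_clean$feature_id, rk_dirty$feature_id)
  expect_identical(attr(curve, "fold_rankings")[[2]]$feature_id, rk_clean$feature_id)
})

test_that("a dominant planted feature drives the curve high at r = 1", {
  withr::with_seed(702, {
    n <- 60
    lab <- rep(c("negative", "positive"), each = n / 2)
    v <- matrix(rnorm(10 * n), 10, n,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:n)))
    v["f5", ] <- ifelse(lab == "positive", 3, -3) + rnorm(n, 0, 0.3)
  })
  d <- make_ld(v, lab)
  curve <- accuracy_curve(d, r_max = 4, k = 5, seed = 4)
  expect_gte(curve$mean_acc[1], 0.95)
  expect_gte(min(curve$mean_acc), 0.85)  # stays near ceiling as r grows
  fit <- fit_fs_svm(d, r_max = 4, k = 5, seed = 4)
  expect_equal(fit$r_star, 1L)           # smallest sufficient model wins
  expect_equal(fit$model$features, "f5")
})

test_that("label-independent features give chance-level curves", {
  d <- random_ld(n = 60, p = 8, seed = 703, prior = 0.6)
  curve <- accuracy_curve(d, r_max = 3, k = 5, seed = 5)
  prior <- max(table(d$labels$label)) / 60
  # every mean within binomial noise of the majority rate
  expect_true(all(abs(curve$mean_acc - prior) <= 3 * sqrt(prior * (1 - prior) / 60) + 0.1))
})

test_that("fitting is deterministic end to end", {
  d <- random_ld(n = 40, p = 6, seed = 704)
  f1 <- fit_fs_svm(d, r_max = 3, k = 4, seed = 9)
  f2 <- fit_fs_svm(d, r_max = 3, k = 4, seed = 9)
  expect_identical(f1$r_star, f2$r_star)
  expect_identical(f1$model$weights, f2$model$weights)
  expect_identical(f1$ranking$feature_id, f2$ranking$feature_id)
  expect_identical(tibble::as_tibble(f1$curve), tibble::as_tibble(f2$curve))
  expect_equal(f1$cv_accuracy[["mean"]], f1$curve$mean_acc[f1$r_star])
  expect_length(f1$model$features, f1$r_star)
})

test_that("tidy and glance summarize fitted objects", {
  d <- random_ld(n = 40, p = 6, seed = 705)
  f <- fit_fs_svm(d, r_max = 3, k = 4, seed = 10)
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "rank", "relevance", "mrmr_score") %in% names(td)))
  expect_equal(nrow(td), f$r_star + 1)  # terms plus threshold row
  gl <- glance(f)
  expect_equal(gl$r_star, f$r_star)
  expect_equal(gl$cv_accuracy, f$cv_accuracy[["mean"]])
  expect_s3_class(autoplot(f), "ggplot")
  expect_s3_class(autoplot(f$ranking), "ggplot")
})
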