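# small in-code fixtures shared across test files

# features x samples matrix -> expr_mat (stage chosen to skip the
# nonnegativity invariant when values are signed)
make_em <- function(v, stage = "raw", annotated = TRUE) {
  if (is.null(rownames(v))) rownames(v) <- paste0("f", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- paste0("s", seq_len(ncol(v)))
  expr_mat(v, annotated = annotated, stage = stage)
}

make_ld <- function(v, labels, stage = "zscore") {
  m <- make_em(v, stage = stage)
  labeled_dataset(m, tibble::tibble(
    sample_id = sample_ids(m),
    label = factor(labels, levels = c("negative", "positive"))
  ))
}

# random labeled dataset: p standard-normal features, n samples
random_ld <- function(n, p, seed, prior = 0.5) {
  withr::with_seed(seed, {
    y <- ifelse(runif(n) < prior, "positive", "negative")
    while (length(unique(y)) < 2 || min(table(y)) < 2) {
      y <- ifelse(runif(n) < prior, "positive", "negative")
    }
    v <- matrix(rnorm(p * n), nrow = p)
    make_ld(v, y)
  })
}

# full normalization of a raw synthetic cohort down to z-scores; the
# log-ratio step is included because the generator plants Gaussian signal on
# log scale (where the two-Gaussian accuracy oracle applies)
prep_cohort <- function(d) {
  ld_transform(d, function(m) {
    m <- suppressMessages(impute_missing(filter_features(m, require_annotation = FALSE)))
    normalize_chain(m, c("floor", "per_array", "per_feature", "log_ratio", "zscore"))
  })
}

# analytic MI (bits) of a two-component unit-variance Gaussian mixture,
# integrated from the closed-form densities (independent oracle)
gaussian_mixture_mi <- function(delta, p_pos = 0.5) {
  px <- function(x) p_pos * dnorm(x, delta) + (1 - p_pos) * dnorm(x, 0)
  comp <- function(mu, pc) {
    stats::integrate(function(x) {
      f <- dnorm(x, mu)
      ifelse(f > 0, pc * f * log2(f / px(x)), 0)
    }, mu - 10, mu + 10, rel.tol = 1e-9)$value
  }
  comp(0, 1 - p_pos) + comp(delta, p_pos)
}

# plug-in discrete mutual information in bits (independent oracle)
discrete_mi <- function(x, y) {
  tab <- table(x, y) / length(x)
  px <- rowSums(tab); py <- colSums(tab)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log2(tab[i, j] / (px[i] * py[j]))
  }
  unname(mi)
}

# naive mRMR: re-evaluates the greedy criterion from scratch at every step
# using the same MI primitives but none of mrmr_rank()'s bookkeeping
naive_mrmr <- function(d, top_k) {
  X <- t(em_matrix(d$matrix))
  y <- ifelse(d$labels$label == "positive", 1L, 0L)
  rel <- vapply(seq_len(ncol(X)), function(j) parzen_mi(X[, j], y), numeric(1))
  selected <- integer(0)
  for (t in seq_len(top_k)) {
    remaining <- setdiff(seq_len(ncol(X)), selected)
    crit <- vapply(remaining, function(f) {
      if (t == 1) return(rel[f])
      rel[f] - mean(vapply(selected, function(s) feature_mi(X[, f], X[, s]),
                           numeric(1)))
    }, numeric(1))
    selected <- c(selected, remaining[which.max(crit)])
  }
  colnames(X)[selected]
}
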