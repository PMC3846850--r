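#' Minimum-redundancy / maximum-relevance feature ranking
#'
#' Greedy mRMR ordering in the mutual-information difference (MID) form. The
#' first feature is the one with maximal relevance I(f; C). Thereafter, with
#' t features already selected, the next is the remaining candidate
#' maximizing
#'
#'   I(f; C) - (1/t) * sum over selected s of I(f; s)
#'
#' so a feature highly informative about the class but redundant with what is
#' already in the list is demoted below a less informative, complementary one.
#' All mutual informations are Parzen-window estimates ([parzen_mi()],
#' [feature_mi()]), in bits.
#'
#' Pairwise continuous MI is the expensive part, so for transcriptome-scale
#' inputs the greedy stage can be restricted to a candidate pool of the
#' `pool_size` most relevant features (standard mRMR practice); the default
#' `pool_size = NULL` evaluates the criterion over every remaining feature,
#' which is exact but quadratic.
#'
#' Ties in relevance or mRMR score are broken by input feature order (first
#' wins), making the ranking deterministic.
#'
#' @param d a `labeled_dataset` with no missing or constant features.
#' @param top_k number of features to rank.
#' @param pool_size optional relevance pre-screening size (`NULL` = all).
#' @param redundancy_weight multiplier on the redundancy term; 0 reduces the
#'   ranking to descending relevance.
#' @param n_grid quadrature grid for class-relevance MI.
#' @param pair_grid per-dimension grid for pairwise feature MI.
#' @return A `ranked_features` tibble: `rank`, `feature_id`, `relevance`
#'   (bits) and `mrmr_score` (criterion value at selection time).
#' @export
mrmr_rank <- function(d, top_k, pool_size = NULL, redundancy_weight = 1,
                      n_grid = 512, pair_grid = 64) {
  rel <- relevance_mi(d, n_grid = n_grid)
  p <- nrow(rel)
  if (top_k < 1 || top_k > p) {
    abort(sprintf("`top_k` must be in 1..%d (number of features).", p))
  }
  X <- t(em_matrix(d$matrix))
  relevance <- rel$relevance

  pool <- seq_len(p)
  if (!is.null(pool_size) && pool_size < p) {
    if (pool_size < top_k) abort("`pool_size` must be at least `top_k`.")
    # stable order(): ties keep input feature order; pool kept in input order
    pool <- sort(head(order(-relevance), pool_size))
  }

  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- setNames(numeric(length(pool)), as.character(pool))
  remaining <- pool
  for (t in seq_len(top_k)) {
    if (t == 1) {
      crit <- relevance[remaining]
    } else {
      crit <- relevance[remaining] -
        redundancy_weight * red_sum[as.character(remaining)] / (t - 1)
    }
    pick <- remaining[which.max(crit)]
    selected <- c(selected, pick)
    scores <- c(scores, max(crit))
    remaining <- setdiff(remaining, pick)
    if (t < top_k && redundancy_weight != 0) {
      xs <- X[, pick]
      for (f in remaining) {
        red_sum[as.character(f)] <- red_sum[as.character(f)] +
          feature_mi(X[, f], xs, pair_grid = pair_grid)
      }
    }
  }
  out <- tibble::tibble(
    rank = seq_len(top_k),
    feature_id = rel$feature_id[selected],
    relevance = relevance[selected],
    mrmr_score = scores
  )
  class(out) <- c("ranked_features", class(out))
  attr(out, "unit") <- "bits"
  attr(out, "pool_size") <- if (is.null(pool_size)) p else min(pool_size, p)
  out
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("# ranked_features: top %d of pool %d (MI in %s)\n",
              nrow(x), attr(x, "pool_size"), attr(x, "unit") %||% "bits"))
  NextMethod()
}
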