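#' Microarray normalization chain
#'
#' Four arithmetic steps prepare raw single-channel intensities for analysis:
#'
#' 1. [floor_baseline()] — replace every value below a small positive floor
#'    (default 0.1) with the floor, so later ratios are defined.
#' 2. [normalize_per_array()] — divide each array (sample column) by its own
#'    50th percentile, removing array-to-array brightness differences.
#' 3. [normalize_per_feature()] — divide each feature (probe row) by its
#'    median across samples, putting probes on a common fold-change scale.
#' 4. [zscore()] — standardize each feature to zero mean, unit variance
#'    across the cohort. z-scores are invariant to any positive affine
#'    rescaling of a probe, which is what makes a fixed linear classifier
#'    transferable across labs and platforms.
#'
#' [normalize_chain()] runs the steps in order. [exponentiate()] undoes a log
#' transform for cohorts deposited on log scale, and [log_actb_normalize()]
#' is the single-sample alternative: log expression relative to a
#' housekeeping gene.
#'
#' @name normalize
NULL

add_params <- function(m, ...) {
  p <- attr(m, "norm_params") %||% list()
  utils::modifyList(p, list(...))
}

#' @rdname normalize
#' @param m an `expr_mat`.
#' @param floor positive floor constant (intensity units).
#' @export
floor_baseline <- function(m, floor = 0.1) {
  if (!is.numeric(floor) || floor <= 0) abort("`floor` must be a positive number.",
                                              class = "ersvm_config_error")
  check_stage(m, "raw", "floor_baseline")
  v <- em_matrix(m)
  v[!is.na(v) & v < floor] <- floor
  em_with_values(m, v, stage = "floored", norm_params = add_params(m, floor = floor))
}

#' @rdname normalize
#' @export
normalize_per_array <- function(m) {
  check_stage(m, "floored", "normalize_per_array")
  v <- em_matrix(m)
  med <- apply(v, 2, median, na.rm = TRUE)
  if (any(med <= 0)) abort("Array median <= 0; apply floor_baseline() first.")
  em_with_values(m, sweep(v, 2, med, "/"), stage = "array_norm")
}

#' @rdname normalize
#' @export
normalize_per_feature <- function(m) {
  check_stage(m, "array_norm", "normalize_per_feature")
  v <- em_matrix(m)
  med <- apply(v, 1, median, na.rm = TRUE)
  if (any(med <= 0)) {
    abort(paste0("Feature median <= 0 for: ",
                 paste(rownames(v)[med <= 0], collapse = ", ")))
  }
  em_with_values(m, sweep(v, 1, med, "/"), stage = "feature_norm",
                 norm_params = add_params(m, per_feature_median = setNames(med, rownames(v))))
}

#' Per-feature z-score transform
#'
#' Standardizes each feature to mean 0, sd 1 across the cohort, using the
#' population standard deviation (divisor n). Usable either as the final
#' step of the chain or standalone on an external cohort — z-scores are
#' always refit on the cohort at hand, never carried over from training
#' data. Fitted means and sds are stored and retrievable via [norm_params()].
#'
#' @param m an `expr_mat` at any stage except `zscore`/`log_actb`; missing
#'   values must have been imputed.
#' @return The transformed `expr_mat` (stage `"zscore"`).
#' @export
zscore <- function(m) {
  v <- em_matrix(m)
  if (anyNA(v)) abort("zscore() requires a complete matrix; impute_missing() first.")
  mu <- rowMeans(v)
  sdev <- sqrt(rowMeans((v - mu)^2))
  if (any(sdev == 0)) {
    abort(paste0("Constant feature(s), z-score undefined: ",
                 paste(rownames(v)[sdev == 0], collapse = ", ")),
          class = "ersvm_constant_feature")
  }
  em_with_values(m, (v - mu) / sdev, stage = "zscore",
                 norm_params = add_params(m, mean = setNames(mu, rownames(v)),
                                          sd = setNames(sdev, rownames(v)),
                                          sd_type = "population"))
}

#' Log-transform median-centered ratios
#'
#' Optional step between the per-feature scaling and the z-score: log2 of the
#' fold-change ratios. Raw intensities are approximately log-normal, so
#' z-scoring them directly leaves each feature heavily right-skewed; taking
#' logs first makes the class-conditional distributions near-Gaussian, which
#' suits margin classifiers and matches how expression fold changes are
#' usually analyzed. The chain is equally valid without it, and the default
#' chain omits it.
#'
#' @param m an `expr_mat` at stage `"feature_norm"` (strictly positive ratios).
#' @return The log2-ratio `expr_mat`, stage `"log_ratio"`.
#' @export
log_ratio <- function(m) {
  check_stage(m, "feature_norm", "log_ratio")
  v <- em_matrix(m)
  if (any(v <= 0, na.rm = TRUE)) abort("Ratios must be strictly positive.")
  em_with_values(m, log2(v), stage = "log_ratio")
}

#' @rdname normalize
#' @param base exponentiation base (must be positive); natural base default.
#' @export
exponentiate <- function(m, base = exp(1)) {
  if (!is.numeric(base) || base <= 0) abort("`base` must be positive.",
                                            class = "ersvm_config_error")
  check_stage(m, "raw", "exponentiate")
  em_with_values(m, base^em_matrix(m), stage = "raw")
}

#' Housekeeping-gene log-ratio normalization
#'
#' The single-sample alternative to the cohort-level chain: for each target
#' probe, log(expression) minus log(expression of a housekeeping gene, ACTB
#' by convention) in the same sample. Any cohort-wide multiplicative factor
#' on a sample cancels in the ratio, so no reference population is needed.
#'
#' @param m an `expr_mat` at stage `"raw"`, strictly positive where used.
#' @param target_features probes to keep.
#' @param housekeeping_feature reference probe id.
#' @param base logarithm base (natural default).
#' @return An `expr_mat` over `target_features` only, stage `"log_actb"`.
#' @export
log_actb_normalize <- function(m, target_features, housekeeping_feature,
                               base = exp(1)) {
  check_stage(m, "raw", "log_actb_normalize")
  v <- em_matrix(m)
  missing <- setdiff(c(target_features, housekeeping_feature), rownames(v))
  if (length(missing) > 0) {
    abort(paste0("Feature(s) not in matrix: ", paste(missing, collapse = ", ")))
  }
  used <- v[c(target_features, housekeeping_feature), , drop = FALSE]
  if (anyNA(used) || any(used <= 0)) {
    abort("log_actb_normalize() requires strictly positive, non-missing values in all used cells.")
  }
  hk <- v[housekeeping_feature, ]
  out <- sweep(log(v[target_features, , drop = FALSE], base = base), 2,
               log(hk, base = base), "-")
  keep <- match(target_features, m$feature_id)
  new_expr_mat(out, annotated = m$annotated[keep],
               present_count = m$present_count[keep], stage = "log_actb",
               norm_params = add_params(m, housekeeping = housekeeping_feature,
                                        log_base = base))
}

#' @rdname normalize
#' @param steps subset of `c("floor", "per_array", "per_feature", "log_ratio",
#'   "zscore")`, applied in that order; `log_ratio` is optional (see
#'   [log_ratio()]) and not part of the default chain.
#' @export
normalize_chain <- function(m, steps = c("floor", "per_array", "per_feature", "zscore"),
                            floor = 0.1) {
  steps <- match.arg(steps, c("floor", "per_array", "per_feature", "log_ratio", "zscore"),
                     several.ok = TRUE)
  for (s in steps) {
    m <- switch(s,
      floor = floor_baseline(m, floor = floor),
      per_array = normalize_per_array(m),
      per_feature = normalize_per_feature(m),
      log_ratio = log_ratio(m),
      zscore = zscore(m)
    )
  }
  m
}
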