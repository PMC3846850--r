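#' Filter features by presence and annotation
#'
#' Keeps exactly the features measured (non-missing) in at least `min_present`
#' samples and, optionally, carrying a database annotation. This is the
#' standard pre-analysis filter for single-channel arrays: probes without an
#' accession or detected in too few arrays carry little usable signal. The
#' default presence cutoff is `ceiling(0.25 * n_samples)`, generalizing the
#' common "present in a quarter of the cohort" rule; pass an integer to pin it
#' exactly (44 of 176, say).
#'
#' @param m an `expr_mat`.
#' @param min_present minimum number of non-missing samples; default
#'   `ceiling(0.25 * n_samples)`.
#' @param require_annotation drop unannotated features?
#' @return The filtered `expr_mat`; sample set and feature order unchanged.
#' @export
filter_features <- function(m, min_present = NULL, require_annotation = TRUE) {
  n <- length(sample_ids(m))
  if (is.null(min_present)) min_present <- ceiling(0.25 * n)
  if (min_present < 0) abort("`min_present` must be >= 0.")
  keep <- m$present_count >= min_present
  if (require_annotation) keep <- keep & m$annotated
  if (!any(keep)) abort("Filtering removed every feature.", class = "ersvm_filter_error")
  out <- m[keep, ]
  attr(out, "stage") <- stage(m)
  attr(out, "norm_params") <- attr(m, "norm_params")
  class(out) <- class(m)
  out
}

#' Impute remaining missing values with per-feature medians
#'
#' After presence filtering, any residual missing entries are replaced by the
#' median of the feature's observed values — a robust choice that leaves the
#' per-feature median scaling step unaffected. The number of imputed cells is
#' reported.
#'
#' @param m an `expr_mat`.
#' @return The `expr_mat` with no missing values; `present_count` untouched
#'   (it keeps recording how many samples were actually measured).
#' @export
impute_missing <- function(m) {
  v <- em_matrix(m)
  n_missing <- sum(is.na(v))
  if (n_missing == 0) return(m)
  all_na <- rowSums(!is.na(v)) == 0
  if (any(all_na)) {
    abort(paste0("Cannot impute features with no observed values: ",
                 paste(rownames(v)[all_na], collapse = ", ")))
  }
  med <- apply(v, 1, median, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- med[idx[, 1]]
  inform(sprintf("Imputed %d missing value(s) with per-feature medians.", n_missing))
  em_with_values(m, v, stage = stage(m))
}
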