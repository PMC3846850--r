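#' The fixed three-gene ER-status classifier
#'
#' A published linear rule over cohort-level z-scores of three probes —
#' AW972815 (oligo A_32_P104334), GATA3 (A_23_P75056) and CA12
#' (A_23_P372234) — with coefficients -0.2466, +2.2165 and +1.2934. GATA3
#' and CA12 are up-regulated in ER-positive tumors (large positive weights);
#' the AW972815 transcript enters with a small negative weight. The intercept
#' of the original rule is not recoverable, so the default threshold is 0 on
#' z-scored inputs; override it, or re-derive one from a labeled cohort with
#' [refit_threshold()].
#'
#' @format `er3_probes` is a named character vector (canonical Agilent oligo
#'   ids, named `aw972815`, `gata3`, `ca12`); `er3_coefficients` is the
#'   matching numeric weight vector, named by probe id.
#' @export
er3_probes <- c(aw972815 = "A_32_P104334",
                gata3 = "A_23_P75056",
                ca12 = "A_23_P372234")

#' @rdname er3_probes
#' @export
er3_coefficients <- c(A_32_P104334 = -0.2466,
                      A_23_P75056 = 2.2165,
                      A_23_P372234 = 1.2934)

#' @rdname er3_probes
#' @param threshold intercept added to the linear score; a sample is called
#'   positive when the score (including the intercept) is `>= 0`.
#' @return `eq3_model()` returns the classifier as a [linear_model][train_linear_svm].
#' @export
eq3_model <- function(threshold = 0) {
  new_linear_model(features = unname(er3_probes),
                   weights = er3_coefficients,
                   threshold = threshold, training_stage = "zscore")
}

#' Score three-gene z-scores
#'
#' Pure linear scoring: `-0.2466 * z_AW972815 + 2.2165 * z_GATA3 +
#' 1.2934 * z_CA12 + threshold`.
#'
#' @param z numeric vector of three z-scores in probe order (AW972815, GATA3,
#'   CA12), or a matrix/data frame with three such columns (named by probe id
#'   if not in order).
#' @param threshold intercept (default 0).
#' @return Numeric score(s).
#' @export
eq3_score <- function(z, threshold = 0) {
  w <- unname(er3_coefficients)
  if (is.null(dim(z))) {
    if (length(z) != 3) abort("`z` must supply exactly three z-scores.")
    if (!is.null(names(z))) z <- z[unname(er3_probes)]
    if (anyNA(z)) abort("Missing z-score for one of the three probes.")
    return(sum(w * z) + threshold)
  }
  z <- as.matrix(z)
  if (!is.null(colnames(z)) && all(er3_probes %in% colnames(z))) {
    z <- z[, unname(er3_probes), drop = FALSE]
  }
  if (ncol(z) != 3) abort("`z` must have exactly three columns.")
  drop(z %*% w) + threshold
}

#' Bundled cross-platform probe map
#'
#' The three canonical Agilent probes mapped to their closest Affymetrix
#' counterparts (by probe-sequence alignment): 230356_at -> A_32_P104334,
#' 209602_s_at -> A_23_P75056, 203963_at -> A_23_P372234. Shipped as a
#' plain-text table; `er3_probe_map("agilent")` returns the identity map.
#'
#' @param platform `"affymetrix"` or `"agilent"` (identity).
#' @return Tibble with columns `source` (platform probe id) and `target`
#'   (canonical Agilent id).
#' @export
er3_probe_map <- function(platform = c("affymetrix", "agilent")) {
  platform <- match.arg(platform)
  if (platform == "agilent") {
    return(tibble::tibble(source = unname(er3_probes), target = unname(er3_probes)))
  }
  path <- system.file("extdata", "affymetrix_probe_map.tsv", package = "ersvm")
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}

#' Rename platform probes to the canonical ids
#'
#' Extracts the mapped probes from a cohort and renames them to the canonical
#' (Agilent) ids the classifier is written in. The map must be one-to-one and
#' every source probe must be present.
#'
#' @param cohort an `expr_mat`.
#' @param map tibble with `source` and `target` columns.
#' @return An `expr_mat` containing exactly the mapped probes, canonical ids,
#'   in map order.
#' @export
map_probes <- function(cohort, map) {
  stopifnot(all(c("source", "target") %in% names(map)))
  if (anyDuplicated(map$source) || anyDuplicated(map$target)) {
    abort("Probe map must be one-to-one.")
  }
  missing <- setdiff(map$source, feature_ids(cohort))
  if (length(missing) > 0) {
    abort(paste0("Probe(s) missing from cohort: ", paste(missing, collapse = ", ")))
  }
  v <- em_matrix(cohort)[map$source, , drop = FALSE]
  rownames(v) <- map$target
  idx <- match(map$source, cohort$feature_id)
  new_expr_mat(v, annotated = cohort$annotated[idx],
               present_count = cohort$present_count[idx], stage = stage(cohort))
}

#' Apply the three-gene classifier to a cohort
#'
#' Pipeline: optionally exponentiate (for cohorts deposited on log scale),
#' map platform probes to the canonical ids, z-score the three probes on
#' *this* cohort (parameters are always refit on the cohort being classified,
#' never reused from training data), score, and call ER-status. Because
#' z-scoring absorbs any per-probe positive affine distortion, the calls are
#' platform-independent.
#'
#' @param cohort an `expr_mat` containing the (mapped) probes; at least two
#'   samples are needed to fit z-scores.
#' @param probe_map optional `source`/`target` tibble (see [er3_probe_map()]);
#'   `NULL` means the cohort already uses the canonical Agilent ids.
#' @param exponentiate_base if the cohort is on log scale, the base to undo
#'   it with before z-scoring; `NULL` to skip.
#' @param threshold classifier intercept.
#' @return Tibble with `sample_id`, `score` and `er_call` (`"ER+"`/`"ER-"`),
#'   with positive/negative counts attached as attribute `call_counts`.
#' @export
eq3_classify <- function(cohort, probe_map = NULL, exponentiate_base = NULL,
                         threshold = 0) {
  if (length(sample_ids(cohort)) < 2) {
    abort("Need at least 2 samples to fit cohort z-scores.")
  }
  if (!is.null(exponentiate_base)) cohort <- exponentiate(cohort, base = exponentiate_base)
  if (!is.null(probe_map)) cohort <- map_probes(cohort, probe_map)
  missing <- setdiff(unname(er3_probes), feature_ids(cohort))
  if (length(missing) > 0) {
    abort(paste0("Classifier probe(s) missing from cohort: ",
                 paste(missing, collapse = ", ")))
  }
  three <- map_probes(cohort, tibble::tibble(source = unname(er3_probes),
                                             target = unname(er3_probes)))
  z <- zscore(three)
  pred <- predict(eq3_model(threshold), z)
  out <- tibble::tibble(
    sample_id = pred$sample_id,
    score = pred$score,
    er_call = ifelse(pred$label == "positive", "ER+", "ER-")
  )
  attr(out, "call_counts") <- c(positive = sum(out$er_call == "ER+"),
                                negative = sum(out$er_call == "ER-"))
  out
}

#' Re-derive a classifier intercept from a labeled cohort
#'
#' Sweeps candidate intercepts (midpoints between consecutive sorted linear
#' scores) and returns the one maximizing accuracy against the given labels;
#' ties go to the smallest magnitude.
#'
#' @param scores numeric linear scores *without* intercept.
#' @param labels binary labels (positive/negative in any accepted coding).
#' @return The intercept to pass as `threshold`.
#' @export
refit_threshold <- function(scores, labels) {
  y <- as_binary_labels(labels)
  s <- sort(unique(scores))
  cand <- -c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  acc <- vapply(cand, function(t) mean((scores + t >= 0) == (y == 1)), numeric(1))
  best <- cand[acc == max(acc)]
  best[which.min(abs(best))]
}
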