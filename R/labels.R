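#' Read a sample-label table
#'
#' Reads a two-column TSV of `sample_id`, label. Label strings default to the
#' clinical ER-status notation (`"ER+"` / `"ER-"`) and are mapped onto the
#' internal `positive` / `negative` factor; any other string is rejected.
#'
#' @param path file to read.
#' @param positive,negative label strings denoting the two classes.
#' @param header does the file carry a header row? Not auto-detected.
#' @return A tibble with columns `sample_id` and `label`
#'   (factor, levels `negative`, `positive`).
#' @export
read_labels <- function(path, positive = "ER+", negative = "ER-", header = FALSE) {
  tab <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE, skip = if (header) 1L else 0L)
  if (ncol(tab) != 2) abort("Label file must have exactly two columns.",
                            class = "ersvm_format_error")
  names(tab) <- c("sample_id", "label")
  bad <- setdiff(unique(tab$label), c(positive, negative))
  if (length(bad) > 0) {
    abort(paste0("Unknown label string(s): ", paste(bad, collapse = ", "),
                 " (expected '", positive, "' or '", negative, "')."),
          class = "ersvm_format_error")
  }
  if (anyDuplicated(tab$sample_id)) {
    abort(paste0("Duplicate sample ids in label file: ",
                 paste(unique(tab$sample_id[duplicated(tab$sample_id)]), collapse = ", ")),
          class = "ersvm_format_error")
  }
  tibble::tibble(
    sample_id = tab$sample_id,
    label = factor(ifelse(tab$label == positive, "positive", "negative"),
                   levels = c("negative", "positive"))
  )
}

#' Pair an expression matrix with binary class labels
#'
#' Joins a labels table onto an [expr_mat] and computes the empirical class
#' prior. Every sample in the matrix must be labeled; samples listed in
#' `labels` but absent from the matrix trigger an error naming them.
#'
#' @param matrix an `expr_mat`.
#' @param labels tibble with `sample_id` and `label` columns (as produced by
#'   [read_labels()]), or a named character/factor vector.
#' @return A `labeled_dataset`: list with `$matrix`, `$labels` (ordered as the
#'   matrix samples) and `$prior` (named numeric summing to 1).
#' @export
labeled_dataset <- function(matrix, labels) {
  if (!is.data.frame(labels)) {
    labels <- tibble::tibble(sample_id = names(labels),
                             label = factor(as.character(labels),
                                            levels = c("negative", "positive")))
  }
  sids <- sample_ids(matrix)
  extra <- setdiff(labels$sample_id, sids)
  if (length(extra) > 0) {
    abort(paste0("Labeled samples missing from the matrix: ",
                 paste(extra, collapse = ", ")), class = "ersvm_join_error")
  }
  unlabeled <- setdiff(sids, labels$sample_id)
  if (length(unlabeled) > 0) {
    abort(paste0("Samples without a label: ", paste(unlabeled, collapse = ", ")),
          class = "ersvm_join_error")
  }
  lab <- labels[match(sids, labels$sample_id), ]
  counts <- table(lab$label)
  prior <- as.numeric(counts) / length(sids)
  names(prior) <- names(counts)
  structure(list(matrix = matrix, labels = lab, prior = prior),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("# labeled_dataset: %d features x %d samples, stage '%s'\n",
              nrow(x$matrix), nrow(x$labels), stage(x$matrix)))
  cat(sprintf("# prior: negative %.4f, positive %.4f\n",
              x$prior[["negative"]], x$prior[["positive"]]))
  invisible(x)
}

# restrict a labeled dataset to a sample subset (prior recomputed)
ld_subset <- function(d, ids) {
  keep <- c(meta_cols, ids)
  m <- d$matrix[, keep]
  attr(m, "stage") <- stage(d$matrix)
  attr(m, "norm_params") <- attr(d$matrix, "norm_params")
  class(m) <- class(d$matrix)
  labeled_dataset(m, d$labels[d$labels$sample_id %in% ids, ])
}

# labels as 0/1 integer vector aligned with matrix samples (positive = 1)
ld_y01 <- function(d) as.integer(d$labels$label == "positive")

#' Apply a transformation to the matrix of a labeled dataset
#'
#' Convenience wrapper so normalization verbs chain over labeled data, e.g.
#' `d |> ld_transform(zscore)`.
#'
#' @param d a `labeled_dataset`.
#' @param f a function `expr_mat -> expr_mat`.
#' @param ... passed to `f`.
#' @export
ld_transform <- function(d, f, ...) {
  d$matrix <- f(d$matrix, ...)
  d
}
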