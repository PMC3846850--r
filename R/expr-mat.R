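#' Expression matrix objects
#'
#' An `expr_mat` is a tibble holding a features-by-samples expression table:
#' a `feature_id` column, an `annotated` flag (does the probe carry a database
#' accession), a `present_count` column (number of samples with a non-missing
#' measurement), and one numeric column per sample. A `stage` attribute tracks
#' where the matrix sits in the normalization chain: `raw`, `floored`,
#' `array_norm`, `feature_norm`, `zscore` or `log_actb`.
#'
#' @param values numeric matrix (features in rows) with feature ids as
#'   rownames and sample ids as colnames, or a data frame with a `feature_id`
#'   first column.
#' @param annotated logical vector (recycled) flagging annotated features.
#' @param stage normalization stage of the values.
#' @return An `expr_mat` tibble.
#' @export
expr_mat <- function(values, annotated = TRUE, stage = "raw") {
  if (is.data.frame(values)) {
    stopifnot("feature_id" %in% names(values))
    ids <- as.character(values$feature_id)
    mat <- as.matrix(values[setdiff(names(values), c("feature_id", "annotated", "present_count"))])
    rownames(mat) <- ids
    if ("annotated" %in% names(values)) annotated <- as.logical(values$annotated)
  } else {
    mat <- as.matrix(values)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    abort("`values` must carry feature ids as rownames and sample ids as colnames.")
  }
  annotated <- rep_len(as.logical(annotated), nrow(mat))
  new_expr_mat(mat, annotated = annotated,
               present_count = rowSums(!is.na(mat)), stage = stage)
}

meta_cols <- c("feature_id", "annotated", "present_count")
norm_stages <- c("raw", "floored", "array_norm", "feature_norm", "log_ratio",
                 "zscore", "log_actb")

new_expr_mat <- function(mat, annotated, present_count, stage,
                         norm_params = NULL, validate = TRUE) {
  # check before tibble construction, which would silently repair duplicates
  if (anyDuplicated(rownames(mat))) {
    abort(paste0("Duplicate feature ids: ",
                 paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", ")),
          class = "ersvm_format_error")
  }
  if (anyDuplicated(colnames(mat))) {
    abort(paste0("Duplicate sample ids: ",
                 paste(unique(colnames(mat)[duplicated(colnames(mat))]), collapse = ", ")),
          class = "ersvm_format_error")
  }
  out <- tibble::tibble(
    feature_id = rownames(mat),
    annotated = annotated,
    present_count = as.integer(present_count)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(mat, .name_repair = "minimal"))
  attr(out, "stage") <- stage
  attr(out, "norm_params") <- norm_params
  class(out) <- c("expr_mat", class(tibble::tibble()))
  if (validate) validate_expr_mat(out)
  out
}

validate_expr_mat <- function(m) {
  fid <- m$feature_id
  sid <- sample_ids(m)
  if (anyDuplicated(fid)) {
    abort(paste0("Duplicate feature ids: ",
                 paste(unique(fid[duplicated(fid)]), collapse = ", ")),
          class = "ersvm_format_error")
  }
  if (anyDuplicated(sid)) {
    abort(paste0("Duplicate sample ids: ",
                 paste(unique(sid[duplicated(sid)]), collapse = ", ")),
          class = "ersvm_format_error")
  }
  st <- stage(m)
  if (!st %in% norm_stages) abort(paste0("Unknown stage: ", st))
  v <- em_matrix(m)
  if (st == "floored") {
    fl <- (attr(m, "norm_params") %||% list())$floor %||% 0
    if (any(v < fl, na.rm = TRUE)) {
      abort("Stage 'floored' requires all intensities at or above the floor.")
    }
  }
  if (any(m$present_count < 0) || any(m$present_count > length(sid))) {
    abort("present_count must lie in 0..n_samples.")
  }
  invisible(m)
}

#' @export
#' @rdname expr_mat
#' @param m an `expr_mat`.
em_matrix <- function(m) {
  v <- as.matrix(m[setdiff(names(m), meta_cols)])
  rownames(v) <- m$feature_id
  storage.mode(v) <- "double"
  v
}

#' @export
#' @rdname expr_mat
sample_ids <- function(m) setdiff(names(m), meta_cols)

#' @export
#' @rdname expr_mat
feature_ids <- function(m) m$feature_id

#' @export
#' @rdname expr_mat
stage <- function(m) attr(m, "stage") %||% "raw"

#' Normalization parameters fitted by the chain
#'
#' Returns the parameters accumulated so far (floor constant, per-feature
#' medians from the per-feature scaling step, per-feature mean/sd from the
#' z-score step, and the sd convention used).
#'
#' @param m an `expr_mat` that has been through one or more normalization steps.
#' @return A list, or `NULL` if no step stored parameters yet.
#' @export
norm_params <- function(m) attr(m, "norm_params")

# rebuild an expr_mat with new values, carrying metadata forward
em_with_values <- function(m, v, stage, norm_params = attr(m, "norm_params")) {
  new_expr_mat(v, annotated = m$annotated, present_count = m$present_count,
               stage = stage, norm_params = norm_params)
}

check_stage <- function(m, allowed, op) {
  if (!stage(m) %in% allowed) {
    abort(paste0(op, "() expects stage ", paste(allowed, collapse = "/"),
                 " but got '", stage(m), "'."), class = "ersvm_stage_error")
  }
  invisible(m)
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("# expr_mat: %d features x %d samples, stage '%s'\n",
              nrow(x), length(sample_ids(x)), stage(x)))
  NextMethod()
}

#' Read a tab-delimited expression matrix
#'
#' Expects a TSV whose first column holds feature ids and whose header row
#' holds sample ids (`orientation = "features_in_rows"`, the series-matrix
#' convention) or the transpose. Empty cells are treated as missing values,
#' distinct from zero; `present_count` records the number of non-missing
#' samples per feature. An optional logical column named `annotated` is read
#' as the per-feature annotation flag; absent it, all features are flagged
#' annotated.
#'
#' @param path file to read.
#' @param orientation which dimension is in rows.
#' @return An `expr_mat` at stage `"raw"`.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("features_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE,
                         name_repair = "minimal")
  if (ncol(raw) < 2) abort("Expected at least one id column and one data column.",
                           class = "ersvm_format_error")
  ids <- raw[[1]]
  ann <- NULL
  if ("annotated" %in% names(raw)[-1]) {
    ann <- parse_logical_col(raw[["annotated"]], path)
    raw[["annotated"]] <- NULL
  }
  cell <- as.matrix(raw[-1])
  num <- suppressWarnings(matrix(as.numeric(ifelse(cell == "", NA, cell)),
                                 nrow = nrow(cell), dimnames = dimnames(cell)))
  bad <- which(is.na(num) & cell != "", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    abort(sprintf("Non-numeric cell '%s' at row %d (id '%s'), column '%s'.",
                  cell[b[1], b[2]], b[1], ids[b[1]], colnames(cell)[b[2]]),
          class = "ersvm_format_error")
  }
  rownames(num) <- ids
  if (orientation == "samples_in_rows") {
    num <- t(num)
    ann <- NULL
  }
  if (is.null(ann)) ann <- rep(TRUE, nrow(num))
  new_expr_mat(num, annotated = ann, present_count = rowSums(!is.na(num)),
               stage = "raw")
}

parse_logical_col <- function(x, path) {
  out <- dplyr::case_when(
    toupper(x) %in% c("TRUE", "T", "1") ~ TRUE,
    toupper(x) %in% c("FALSE", "F", "0") ~ FALSE,
    .default = NA
  )
  if (anyNA(out)) abort(paste0("Unparseable 'annotated' flag in ", path),
                        class = "ersvm_format_error")
  out
}

#' Write an expression matrix as TSV
#'
#' Missing values are written as empty cells; doubles are written with full
#' round-trip precision, so `read_expression_matrix()` recovers the matrix
#' bit-for-bit. The annotation flag is emitted only when some feature is
#' unannotated.
#'
#' @param m an `expr_mat`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  v <- em_matrix(m)
  out <- tibble::tibble(feature_id = rownames(v))
  if (!all(m$annotated)) out$annotated <- m$annotated
  out <- dplyr::bind_cols(out, tibble::as_tibble(v, .name_repair = "minimal"))
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}
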