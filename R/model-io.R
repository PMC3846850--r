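#' Read and write linear models as JSON
#'
#' The on-disk schema is `{features, weights, threshold, stage_expected,
#' provenance}`; weights are stored at full precision so a model round-trips
#' exactly.
#'
#' @param m a `linear_model`.
#' @param path file path.
#' @param provenance free-text provenance string stored with the model.
#' @return `write_model()` returns `path` invisibly; `read_model()` a
#'   `linear_model`.
#' @export
write_model <- function(m, path, provenance = "") {
  stopifnot(inherits(m, "linear_model"))
  obj <- list(
    features = m$features,
    weights = unname(m$weights),
    threshold = m$threshold,
    stage_expected = m$training_stage,
    provenance = provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_linear_model(features = obj$features,
                   weights = setNames(as.numeric(obj$weights), obj$features),
                   threshold = as.numeric(obj$threshold),
                   training_stage = obj$stage_expected %||% "zscore")
}
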