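#' Run a declarative analysis pipeline
#'
#' Executes the stages named in a config (JSON file or list) in the fixed
#' order `simulate`, `filter`, `normalize`, `rank`, `train`, `predict`,
#' `er3`; only stages present in the config run. Every artifact written to
#' `out_dir` gets a JSON provenance sidecar recording input checksums, the
#' stage parameters, the seed and the package version, so a run can be
#' reproduced or audited. Inputs are never mutated; reruns of the same config
#' produce byte-identical artifacts.
#'
#' Config blocks:
#' \describe{
#'   \item{simulate}{[synthetic_config()] fields; writes `sim_matrix.tsv`,
#'     `sim_labels.tsv`, `sim_truth.json`.}
#'   \item{input}{alternative to simulate: `matrix` (TSV path) and optionally
#'     `labels`.}
#'   \item{filter}{`min_present`, `require_annotation`; missing values are
#'     imputed afterwards.}
#'   \item{normalize}{`steps` (default full chain), `floor`.}
#'   \item{rank}{`top_k`; writes `ranking.tsv`.}
#'   \item{train}{`r_max`, `k`, `seed`, `c_param`; writes `model.json`,
#'     `curve.tsv`, `selected_features.txt`.}
#'   \item{predict}{`matrix` (TSV path, defaults to the working matrix);
#'     writes `predictions.tsv`.}
#'   \item{er3}{`platform`, `exponentiate_base`, `threshold`; writes
#'     `er3_calls.tsv`.}
#' }
#'
#' @param config list or path to a JSON config file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a character vector of artifact paths.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(path, params, inputs = character(0)) {
    side <- paste0(path, ".provenance.json")
    checksums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
    jsonlite::write_json(list(package = "ersvm",
                              version = as.character(utils::packageVersion("ersvm")),
                              params = params, input_md5 = checksums),
                         side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <<- c(artifacts, path, side)
    path
  }

  d <- NULL   # labeled_dataset (if labels known)
  m <- NULL   # working expr_mat

  if (!is.null(config$simulate)) {
    cfg <- do.call(synthetic_config, config$simulate)
    d <- generate_cohort(cfg)
    m <- d$matrix
    mp <- file.path(out_dir, "sim_matrix.tsv")
    write_expression_matrix(m, mp)
    emit(mp, config$simulate)
    lp <- file.path(out_dir, "sim_labels.tsv")
    readr::write_tsv(tibble::tibble(
      sample_id = d$labels$sample_id,
      label = ifelse(d$labels$label == "positive", "ER+", "ER-")
    ), lp, col_names = FALSE, progress = FALSE)
    emit(lp, config$simulate)
    tp <- file.path(out_dir, "sim_truth.json")
    jsonlite::write_json(d$truth, tp, auto_unbox = FALSE, pretty = TRUE)
    emit(tp, config$simulate)
  } else if (!is.null(config$input)) {
    if (!file.exists(config$input$matrix)) {
      abort(paste0("Input matrix not found: ", config$input$matrix))
    }
    m <- read_expression_matrix(config$input$matrix)
    if (!is.null(config$input$labels)) {
      if (!file.exists(config$input$labels)) {
        abort(paste0("Labels file not found: ", config$input$labels))
      }
      d <- labeled_dataset(m, read_labels(config$input$labels))
    }
  } else {
    abort("Config must contain a 'simulate' or 'input' block.")
  }

  sync <- function() if (!is.null(d)) d$matrix <<- m

  if (!is.null(config$filter)) {
    fb <- config$filter
    m <- filter_features(m, min_present = fb$min_present,
                         require_annotation = fb$require_annotation %||% TRUE)
    m <- suppressMessages(impute_missing(m))
    sync()
  }
  if (!is.null(config$normalize)) {
    nb <- config$normalize
    m <- normalize_chain(m, steps = nb$steps %||% c("floor", "per_array", "per_feature", "zscore"),
                         floor = nb$floor %||% 0.1)
    sync()
  }
  if (!is.null(config$rank)) {
    if (is.null(d)) abort("'rank' stage needs labels.")
    rk <- mrmr_rank(d, top_k = config$rank$top_k %||% 18,
                    pool_size = config$rank$pool_size)
    rp <- file.path(out_dir, "ranking.tsv")
    readr::write_tsv(tibble::as_tibble(rk), rp, progress = FALSE)
    emit(rp, config$rank)
  }
  if (!is.null(config$train)) {
    if (is.null(d)) abort("'train' stage needs labels.")
    tb <- config$train
    fitted <- fit_fs_svm(d, r_max = tb$r_max %||% 18, k = tb$k %||% 10,
                         seed = tb$seed %||% 1, c_param = tb$c_param %||% 1)
    mp <- file.path(out_dir, "model.json")
    write_model(fitted$model, mp,
                provenance = sprintf("fit_fs_svm r_max=%d k=%d seed=%d",
                                     nrow(fitted$curve), attr(fitted$curve, "k"),
                                     tb$seed %||% 1))
    emit(mp, tb)
    cp <- file.path(out_dir, "curve.tsv")
    readr::write_tsv(tibble::as_tibble(fitted$curve), cp, progress = FALSE)
    emit(cp, tb)
    sp <- file.path(out_dir, "selected_features.txt")
    writeLines(fitted$model$features, sp)
    emit(sp, tb)
    if (!is.null(config$predict)) {
      pm <- if (!is.null(config$predict$matrix)) {
        read_expression_matrix(config$predict$matrix)
      } else m
      pred <- predict(fitted, pm)
      pp <- file.path(out_dir, "predictions.tsv")
      readr::write_tsv(pred, pp, progress = FALSE)
      emit(pp, config$predict)
    }
  }
  if (!is.null(config$er3)) {
    eb <- config$er3
    map <- if (!is.null(eb$platform) && eb$platform != "agilent") {
      er3_probe_map(eb$platform)
    } else NULL
    calls <- eq3_classify(m, probe_map = map,
                          exponentiate_base = eb$exponentiate_base,
                          threshold = eb$threshold %||% 0)
    ep <- file.path(out_dir, "er3_calls.tsv")
    readr::write_tsv(calls, ep, progress = FALSE)
    emit(ep, eb)
  }
  invisible(artifacts)
}
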