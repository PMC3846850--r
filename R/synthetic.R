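#' Synthetic microarray cohort configuration
#'
#' Describes a labeled cohort with the structure of a single-channel
#' breast-tumor expression study: a minority of class-informative probes, a
#' few noisy duplicates of each (the multi-probe-per-gene phenomenon that
#' gives the mRMR redundancy penalty something real to act on), a large
#' background of uninformative probes, one low-variance housekeeping gene,
#' log-normal raw intensities, and per-cell dropout. Defaults mirror a
#' mid-sized training cohort: 200 samples at the 112/176 positive prior,
#' 3 informative probes (class mean shift 2 SD on log scale) with 2
#' redundant copies each, 989 noise probes, presence rate 0.98.
#'
#' @param n_samples number of samples.
#' @param prior_positive P(positive), strictly inside (0, 1).
#' @param n_informative number of class-informative probes.
#' @param effect_size class mean separation, in within-class SD units on log
#'   scale.
#' @param n_redundant_per_informative noisy copies per informative probe.
#' @param redundancy_noise_sd SD of the copy noise (log scale).
#' @param n_noise class-independent probes.
#' @param presence_rate per-cell probability of a measurement being present.
#' @param housekeeping include a stable housekeeping probe (`ACTB`)?
#' @param unannotated_fraction fraction of noise probes flagged unannotated.
#' @param platform_gain_sd,platform_offset_sd,platform_noise_sd platform-B
#'   distortions for [generate_platform_pair()]: per-probe multiplicative
#'   gain (log-normal sigma), additive offset (intensity units) and
#'   measurement noise (log scale).
#' @param seed integer; identical config + seed reproduces the cohort
#'   bit-for-bit.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 200,
                             prior_positive = 112 / 176,
                             n_informative = 3,
                             effect_size = 2,
                             n_redundant_per_informative = 2,
                             redundancy_noise_sd = 0.5,
                             n_noise = 989,
                             presence_rate = 0.98,
                             housekeeping = TRUE,
                             unannotated_fraction = 0,
                             platform_gain_sd = 0.25,
                             platform_offset_sd = 2,
                             platform_noise_sd = 0.2,
                             seed = 1) {
  cfg <- list(n_samples = n_samples, prior_positive = prior_positive,
              n_informative = n_informative, effect_size = effect_size,
              n_redundant_per_informative = n_redundant_per_informative,
              redundancy_noise_sd = redundancy_noise_sd, n_noise = n_noise,
              presence_rate = presence_rate, housekeeping = housekeeping,
              unannotated_fraction = unannotated_fraction,
              platform_gain_sd = platform_gain_sd,
              platform_offset_sd = platform_offset_sd,
              platform_noise_sd = platform_noise_sd, seed = seed)
  if (prior_positive <= 0 || prior_positive >= 1) {
    abort("`prior_positive` must be strictly between 0 and 1.", class = "ersvm_config_error")
  }
  if (presence_rate <= 0 || presence_rate > 1) {
    abort("`presence_rate` must be in (0, 1].", class = "ersvm_config_error")
  }
  if (n_samples < 4) abort("`n_samples` must be at least 4.", class = "ersvm_config_error")
  structure(cfg, class = "synthetic_config")
}

# draw labels with at least 2 per class (z-scoring and folds need both)
draw_labels <- function(n, prior) {
  repeat {
    lab <- factor(ifelse(runif(n) < prior, "positive", "negative"),
                  levels = c("negative", "positive"))
    if (min(table(lab)) >= 2) return(lab)
  }
}

# latent log-intensity matrix (features x samples) plus truth bookkeeping
build_latent <- function(cfg, lab) {
  n <- cfg$n_samples
  inf_ids <- sprintf("INF%02d", seq_len(cfg$n_informative))
  red_ids <- list()
  blocks <- list()
  shift <- ifelse(lab == "positive", cfg$effect_size / 2, -cfg$effect_size / 2)
  for (j in seq_len(cfg$n_informative)) {
    base <- rnorm(1, 6, 1)
    sgn <- if (j %% 2 == 1) 1 else -1  # alternate up/down regulation
    core <- base + sgn * shift + rnorm(n)
    blocks[[inf_ids[j]]] <- core
    if (cfg$n_redundant_per_informative > 0) {
      ids <- sprintf("RED%02d_%d", j, seq_len(cfg$n_redundant_per_informative))
      red_ids[[inf_ids[j]]] <- ids
      for (id in ids) blocks[[id]] <- core + rnorm(n, 0, cfg$redundancy_noise_sd)
    }
  }
  noise_ids <- character(0)
  if (cfg$n_noise > 0) {
    noise_ids <- sprintf("NOISE%04d", seq_len(cfg$n_noise))
    nb <- matrix(rnorm(cfg$n_noise * n, 0, 1), nrow = cfg$n_noise) +
      rnorm(cfg$n_noise, 6, 1)
    for (j in seq_len(cfg$n_noise)) blocks[[noise_ids[j]]] <- nb[j, ]
  }
  hk_id <- character(0)
  if (isTRUE(cfg$housekeeping)) {
    hk_id <- "ACTB"
    blocks[["ACTB"]] <- rnorm(1, 7, 0.5) + rnorm(n, 0, 0.1)
  }
  L <- do.call(rbind, blocks)
  rownames(L) <- names(blocks)
  colnames(L) <- sprintf("S%03d", seq_len(n))
  list(L = L, truth = list(
    informative = inf_ids,
    redundant = red_ids,
    signal_features = c(inf_ids, unlist(red_ids, use.names = FALSE)),
    noise = noise_ids,
    housekeeping = hk_id
  ))
}

finalize_cohort <- function(cfg, L, lab, truth) {
  raw <- exp(L)
  if (cfg$presence_rate < 1) {
    drop <- matrix(runif(length(raw)) >= cfg$presence_rate, nrow = nrow(raw))
    raw[drop] <- NA
  }
  ann <- rep(TRUE, nrow(raw))
  if (cfg$unannotated_fraction > 0 && length(truth$noise) > 0) {
    n_un <- round(cfg$unannotated_fraction * length(truth$noise))
    un <- sample(truth$noise, n_un)
    ann[rownames(raw) %in% un] <- FALSE
  }
  m <- new_expr_mat(raw, annotated = ann, present_count = rowSums(!is.na(raw)),
                    stage = "raw")
  d <- labeled_dataset(m, tibble::tibble(sample_id = colnames(raw), label = lab))
  d$truth <- truth
  d$config <- cfg
  d
}

#' Generate a labeled synthetic cohort
#'
#' Draws labels from the configured prior, plants class-informative probes
#' (log-intensity shifted by `effect_size` SD between classes, sign
#' alternating so both up- and down-regulated markers occur), adds their
#' redundant copies and the uninformative background, exponentiates to raw
#' intensity scale, and applies per-cell dropout. The planted truth rides
#' along as `$truth` so recovery can be scored.
#'
#' @param cfg a [synthetic_config()].
#' @return A `labeled_dataset` (stage `"raw"`) with `$truth` and `$config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    lab <- draw_labels(cfg$n_samples, cfg$prior_positive)
    lt <- build_latent(cfg, lab)
    finalize_cohort(cfg, lt$L, lab, lt$truth)
  })
}

#' Generate a matched two-platform cohort pair
#'
#' Platform A is a cohort as in [generate_cohort()]. Platform B measures the
#' same latent per-sample signals but through a different instrument:
#' per-probe multiplicative gain (log-normal), additive offset, independent
#' measurement noise on log scale, and its own probe naming. The returned
#' probe map translates platform-B ids back to platform-A ids, so
#' platform-B data can be fed to classifiers written against platform A.
#'
#' @param cfg a [synthetic_config()].
#' @return List with `a`, `b` (labeled datasets over the same samples) and
#'   `probe_map` (tibble `source` = B id, `target` = A id).
#' @export
generate_platform_pair <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    lab <- draw_labels(cfg$n_samples, cfg$prior_positive)
    lt <- build_latent(cfg, lab)
    a <- finalize_cohort(cfg, lt$L, lab, lt$truth)
    p <- nrow(lt$L)
    gain <- exp(rnorm(p, 0, cfg$platform_gain_sd))
    offset <- rnorm(p, 0, cfg$platform_offset_sd)
    noisy <- lt$L + matrix(rnorm(length(lt$L), 0, cfg$platform_noise_sd),
                           nrow = p)
    rawb <- pmax(gain * exp(noisy) + offset, 1e-6)
    b_ids <- sprintf("B_%04d", seq_len(p))
    map <- tibble::tibble(source = b_ids, target = rownames(lt$L))
    rownames(rawb) <- b_ids
    if (cfg$presence_rate < 1) {
      dropb <- matrix(runif(length(rawb)) >= cfg$presence_rate, nrow = p)
      rawb[dropb] <- NA
    }
    mb <- new_expr_mat(rawb, annotated = rep(TRUE, p),
                       present_count = rowSums(!is.na(rawb)), stage = "raw")
    b <- labeled_dataset(mb, tibble::tibble(sample_id = colnames(rawb), label = lab))
    b$truth <- lt$truth
    b$config <- cfg
    list(a = a, b = b, probe_map = map)
  })
}
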