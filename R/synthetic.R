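#' Simulation configuration
#'
#' Parameters of the synthetic multi-batch LC-MS acquisition. The defaults
#' emulate a typical plant-extract study: 7 batches, QCs inserted after every
#' 6 experimental injections, biological replicates in sets of three
#' randomized across batches, log-normal feature baselines, multiplicative
#' per-batch offsets with a component shared across features (so batches
#' separate coherently in PCA), a nonlinear within-batch drift curve shared
#' by all features of a batch, pooled-QC intensities that diverge from sample
#' intensities per feature (`qc_bias_log_sd`) and follow the sample drift
#' only partially (`qc_drift_attenuation`), lognormal biological and
#' measurement noise, and limit-of-detection censoring to zero.
#'
#' All effects are multiplicative (log-normal), matching the ratio form of
#' the correction, so a perfect correction is achievable and testable.
#'
#' @param n_batches number of acquisition batches.
#' @param samples_per_batch experimental injections per batch.
#' @param qc_every a QC is inserted after every `qc_every` experimental
#'   injections (and after the final complete block).
#' @param n_features number of detected features.
#' @param groups experimental group labels.
#' @param replicate_size biological replicates per set.
#' @param baseline_log_mean,baseline_log_sd log-scale location/spread of
#'   feature baseline intensities.
#' @param fraction_affected fraction of features carrying group effects.
#' @param effect_log_sd log-fold-change sd of group effects on affected
#'   features. With exactly four groups they are treated as a factorial
#'   stress design — control, stress A, stress B, dual stress (A + B) — with
#'   the secondary stress at 0.4 of this sd, so the stress-A vs dual
#'   comparison is the subtle one; group differences stay deliberately small
#'   relative to batch variation, the regime where correction matters. With
#'   any other group count each non-reference group draws independent
#'   effects.
#' @param batch_offset_shared_log_sd log-sd of the per-batch offset shared by
#'   all features.
#' @param batch_offset_feature_log_sd log-sd of the additional per-batch,
#'   per-feature offset.
#' @param drift_kinds within-batch drift kind per batch, recycled: `"none"`,
#'   `"linear"`, `"smooth"` or `"changepoint"`.
#' @param drift_amplitude drift amplitude as a fraction of the baseline
#'   level.
#' @param qc_bias_log_sd log-sd of the per-feature QC/sample level
#'   divergence.
#' @param qc_drift_attenuation in \[0, 1\]: fraction of the (log) sample
#'   drift that the QCs follow (1 = QCs track the samples exactly).
#' @param bio_log_sd log-sd of biological variation between replicates.
#' @param noise_log_sd log-sd of measurement noise (applies to QCs too).
#' @param lod_threshold absolute intensity below which a value records as 0.
#' @param conditioning_qcs number of column-conditioning QC injections
#'   prepended to the run with role `"conditioning"` (excluded from all
#'   analysis); 0 by default.
#' @param seed master seed; every stochastic draw flows from it in a fixed
#'   documented order, so a config is fully reproducible.
#' @return a validated `SimConfig` (S3 list).
#' @export
simConfig <- function(n_batches = 7, samples_per_batch = 24, qc_every = 6,
                      n_features = 300, groups = c("C", "D", "F", "B"),
                      replicate_size = 3,
                      baseline_log_mean = log(5000), baseline_log_sd = 1.2,
                      fraction_affected = 0.25, effect_log_sd = 0.25,
                      batch_offset_shared_log_sd = 0.4,
                      batch_offset_feature_log_sd = 0.2,
                      drift_kinds = "smooth", drift_amplitude = 0.6,
                      qc_bias_log_sd = 0.5, qc_drift_attenuation = 0.5,
                      bio_log_sd = 0.1, noise_log_sd = 0.15,
                      lod_threshold = 500, conditioning_qcs = 0,
                      seed = 1) {
  cfg <- list(n_batches = as.integer(n_batches),
              samples_per_batch = as.integer(samples_per_batch),
              qc_every = as.integer(qc_every),
              n_features = as.integer(n_features),
              groups = as.character(groups),
              replicate_size = as.integer(replicate_size),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              fraction_affected = fraction_affected,
              effect_log_sd = effect_log_sd,
              batch_offset_shared_log_sd = batch_offset_shared_log_sd,
              batch_offset_feature_log_sd = batch_offset_feature_log_sd,
              drift_kinds = as.character(drift_kinds),
              drift_amplitude = drift_amplitude,
              qc_bias_log_sd = qc_bias_log_sd,
              qc_drift_attenuation = qc_drift_attenuation,
              bio_log_sd = bio_log_sd, noise_log_sd = noise_log_sd,
              lod_threshold = lod_threshold,
              conditioning_qcs = as.integer(conditioning_qcs),
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  .validateSimConfig(cfg)
  cfg
}

.validateSimConfig <- function(cfg) {
  sds <- c("baseline_log_sd", "effect_log_sd", "batch_offset_shared_log_sd",
           "batch_offset_feature_log_sd", "qc_bias_log_sd", "bio_log_sd",
           "noise_log_sd")
  for (s in sds)
    if (is.na(cfg[[s]]) || cfg[[s]] < 0)
      stop("SimConfig: ", s, " must be >= 0", call. = FALSE)
  if (cfg$qc_every < 1) stop("SimConfig: qc_every must be >= 1", call. = FALSE)
  if (cfg$qc_drift_attenuation < 0 || cfg$qc_drift_attenuation > 1)
    stop("SimConfig: qc_drift_attenuation must be in [0, 1]", call. = FALSE)
  if (cfg$n_batches < 1 || cfg$samples_per_batch < 1 || cfg$n_features < 1)
    stop("SimConfig: n_batches, samples_per_batch and n_features must be >= 1",
         call. = FALSE)
  if (cfg$fraction_affected < 0 || cfg$fraction_affected > 1)
    stop("SimConfig: fraction_affected must be in [0, 1]", call. = FALSE)
  if (cfg$lod_threshold < 0)
    stop("SimConfig: lod_threshold must be >= 0", call. = FALSE)
  if (!all(cfg$drift_kinds %in% c("none", "linear", "smooth", "changepoint")))
    stop("SimConfig: drift_kinds must be none/linear/smooth/changepoint",
         call. = FALSE)
  invisible(cfg)
}

#' QC-divergent scenario preset
#'
#' The failure regime for classical QC correction: strong nonlinear
#' within-batch drift (alternating sudden level changes and smooth wander)
#' that the QCs track only weakly (`qc_drift_attenuation = 0.2`), combined
#' with substantial per-feature QC/sample level divergence. Background
#' correction, which estimates the trend from all observations, remains
#' informative here while QC-only trends mislead.
#'
#' @param ... overrides passed on to [simConfig()].
#' @return a `SimConfig`.
#' @export
qcDivergentConfig <- function(...) {
  defaults <- list(drift_kinds = c("changepoint", "smooth"),
                   qc_drift_attenuation = 0.2)
  args <- utils::modifyList(defaults, list(...))
  do.call(simConfig, args)
}

#' Within-batch drift curve
#'
#' A positive multiplier per acquisition position. `"none"` is flat 1;
#' `"linear"` ramps by `amplitude` across the batch (centred at 1);
#' `"smooth"` is the exponential of a lowess-smoothed random walk rescaled to
#' +/- `log(1 + amplitude)`; `"changepoint"` is a level shift of
#' +/- `amplitude` at a random interior position.
#'
#' @param kind drift kind.
#' @param length number of positions.
#' @param amplitude drift amplitude as a fraction of baseline; must leave all
#'   multipliers positive.
#' @param seed optional seed set before the stochastic kinds draw.
#' @return numeric vector of positive multipliers, one per position.
#' @export
driftCurve <- function(kind = c("none", "linear", "smooth", "changepoint"),
                       length, amplitude = 0.5, seed = NULL) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  if (length < 1) stop("drift curve length must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(length)
  curve <- switch(kind,
    none = rep(1, length),
    linear = 1 + amplitude * (t - (length + 1) / 2) / length,
    smooth = {
      if (length == 1) rep(1, length) else {
        s <- cumsum(stats::rnorm(length))
        s <- stats::lowess(t, s, f = 0.4)$y
        s <- s - mean(s)
        mx <- max(abs(s))
        if (mx > 0) s <- s / mx * log1p(amplitude)
        exp(s)
      }
    },
    changepoint = {
      if (amplitude >= 1)
        stop("changepoint amplitude ", amplitude,
             " can produce non-positive multipliers (needs amplitude < 1)",
             call. = FALSE)
      if (length == 1) rep(1, length) else {
        pos <- if (length == 2) 2L else sample(2:length, 1)
        shift <- sample(c(-1, 1), 1) * amplitude
        c(rep(1, pos - 1), rep(1 + shift, length - pos + 1))
      }
    })
  if (any(curve <= 0))
    stop("drift amplitude ", amplitude, " produces non-positive multipliers",
         call. = FALSE)
  curve
}

#' Limit-of-detection censoring
#'
#' @param values numeric vector or matrix of intensities.
#' @param threshold values strictly below it are recorded as 0.
#' @return the censored values.
#' @export
applyLod <- function(values, threshold) {
  if (threshold < 0) stop("LOD threshold must be >= 0", call. = FALSE)
  values[values < threshold] <- 0
  values
}

#' Simulate a multi-batch LC-MS peak matrix with ground truth
#'
#' Builds the acquisition layout (QCs after every `qc_every` experimental
#' injections in each batch, biological replicate sets randomized across
#' batches), then composes observed intensities as
#' `baseline x group effect x biological noise x batch offset x drift x
#' measurement noise`, with QCs using their own per-feature level
#' (`qc_bias`) and an attenuated version of the batch's drift curve, and
#' finally censors values below the limit of detection to zero. All draws
#' derive from `config$seed` in a fixed order, so the result is fully
#' deterministic.
#'
#' @param config a `SimConfig` from [simConfig()].
#' @return list with `matrix` (a [PeakSet-class]) and `truth` (a
#'   `SyntheticTruth` S3 list: `clean_matrix` — the drift-, offset- and
#'   measurement-noise-free intensities per observation x feature;
#'   `drift` — the applied per-observation multiplier; `drift_curves` — the
#'   raw per-batch curves; `batch_offsets` (batch x feature multipliers);
#'   `group_effects` (feature x group, log scale); `qc_bias` (per-feature
#'   multiplier); `config`).
#' @examples
#' sim <- simulateDataset(simConfig(n_batches = 2, samples_per_batch = 12,
#'                                  n_features = 20, seed = 7))
#' sim$matrix
#' @export
simulateDataset <- function(config = simConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  .validateSimConfig(config)
  cfg <- config
  set.seed(cfg$seed)
  nF <- cfg$n_features
  nG <- length(cfg$groups)

  # 1. feature baselines
  base <- stats::rnorm(nF, cfg$baseline_log_mean, cfg$baseline_log_sd)
  # 2. affected features and 3. group effects (reference group = first label)
  nAff <- round(cfg$fraction_affected * nF)
  affected <- sort(sample.int(nF, nAff))
  groupEff <- matrix(0, nF, nG, dimnames = list(NULL, cfg$groups))
  if (nAff && nG == 4) {
    # factorial stress design: control / stress A / stress B / dual (both),
    # with the secondary stress subtler than the primary
    a <- stats::rnorm(nAff, 0, cfg$effect_log_sd)
    b <- stats::rnorm(nAff, 0, 0.4 * cfg$effect_log_sd)
    groupEff[affected, 2] <- a
    groupEff[affected, 3] <- b
    groupEff[affected, 4] <- a + b
  } else if (nAff && nG > 1) {
    groupEff[affected, -1] <- stats::rnorm(nAff * (nG - 1), 0,
                                           cfg$effect_log_sd)
  }
  # 4. per-feature QC level divergence
  qcBias <- stats::rnorm(nF, 0, cfg$qc_bias_log_sd)
  # 5. batch offsets: shared + per-feature component
  uB <- stats::rnorm(cfg$n_batches, 0, cfg$batch_offset_shared_log_sd)
  vBP <- matrix(stats::rnorm(cfg$n_batches * nF, 0,
                             cfg$batch_offset_feature_log_sd),
                cfg$n_batches, nF)
  batchOffsets <- exp(uB + vBP)

  # layout: per batch, blocks of qc_every experimental injections each
  # followed by a QC (QC also closes the final complete block)
  spb <- cfg$samples_per_batch
  nQCb <- spb %/% cfg$qc_every
  obsPerBatch <- spb + nQCb
  layout <- do.call(rbind, lapply(seq_len(cfg$n_batches), function(b) {
    roles <- character(0)
    placed <- 0L
    while (placed < spb) {
      blk <- min(cfg$qc_every, spb - placed)
      roles <- c(roles, rep("experimental", blk),
                 if (blk == cfg$qc_every) "QC")
      placed <- placed + blk
    }
    data.frame(batch = b, role = roles, pos = seq_along(roles))
  }))
  if (cfg$conditioning_qcs > 0) {
    cond <- data.frame(batch = 1L, role = "conditioning",
                       pos = NA_integer_)
    layout <- rbind(cond[rep(1, cfg$conditioning_qcs), ], layout)
  }
  nObs <- nrow(layout)
  layout$run_index <- seq_len(nObs)
  expIdx <- which(layout$role == "experimental")
  nExp <- length(expIdx)

  # 6. drift curves per batch (drawn in batch order)
  kinds <- rep(cfg$drift_kinds, length.out = cfg$n_batches)
  curves <- lapply(seq_len(cfg$n_batches), function(b)
    driftCurve(kinds[b], obsPerBatch, cfg$drift_amplitude))

  # 7. replicate sets cycled over groups/timepoints, randomized across slots
  nSets <- nExp %/% cfg$replicate_size
  setOfSample <- rep(NA_integer_, nExp)
  slot <- sample.int(nExp)
  if (nSets)
    setOfSample[slot[seq_len(nSets * cfg$replicate_size)]] <-
      rep(seq_len(nSets), each = cfg$replicate_size)
  setGroup <- cfg$groups[((seq_len(max(nSets, 1)) - 1) %% nG) + 1]
  setTime <- ((seq_len(max(nSets, 1)) - 1) %/% nG) + 1

  layout$group <- NA_character_
  layout$replicate_set <- NA_character_
  layout$timepoint <- NA_integer_
  hasSet <- !is.na(setOfSample)
  layout$group[expIdx[hasSet]] <- setGroup[setOfSample[hasSet]]
  layout$replicate_set[expIdx[hasSet]] <-
    sprintf("set%03d", setOfSample[hasSet])
  layout$timepoint[expIdx[hasSet]] <- setTime[setOfSample[hasSet]]
  # leftover samples (if replicate_size does not divide the count) still get
  # a group so they contribute to grand means
  layout$group[expIdx[!hasSet]] <- cfg$groups[1]

  # 8. biological replicate noise, 9. measurement noise
  bio <- matrix(0, nObs, nF)
  bio[expIdx, ] <- stats::rnorm(nExp * nF, 0, cfg$bio_log_sd)
  meas <- matrix(stats::rnorm(nObs * nF, 0, cfg$noise_log_sd), nObs, nF)

  isQc <- layout$role %in% c("QC", "conditioning")
  gIdx <- match(layout$group, cfg$groups)
  logClean <- matrix(base, nObs, nF, byrow = TRUE)
  ge <- matrix(0, nObs, nF)
  ge[!isQc, ] <- groupEff[, gIdx[!isQc], drop = FALSE] |> t()
  logClean <- logClean + ge + bio
  logClean[isQc, ] <- logClean[isQc, , drop = FALSE] +
    matrix(qcBias, sum(isQc), nF, byrow = TRUE)
  clean <- exp(logClean)

  driftApplied <- numeric(nObs)
  for (b in seq_len(cfg$n_batches)) {
    bi <- which(layout$batch == b & layout$role != "conditioning")
    cv <- curves[[b]][seq_along(bi)]
    att <- ifelse(layout$role[bi] == "QC", cfg$qc_drift_attenuation, 1)
    driftApplied[bi] <- exp(att * log(cv))
  }
  driftApplied[layout$role == "conditioning"] <- 1

  off <- batchOffsets[layout$batch, , drop = FALSE]
  off[layout$role == "conditioning", ] <- 1
  observed <- clean * off * driftApplied * exp(meas)
  observed <- applyLod(observed, cfg$lod_threshold)

  meta <- data.frame(
    sample_id = sprintf("S%03d", layout$run_index),
    run_index = layout$run_index, batch = layout$batch,
    role = layout$role, group = layout$group,
    replicate_set = layout$replicate_set, timepoint = layout$timepoint,
    stringsAsFactors = FALSE)
  colnames(observed) <- sprintf("M%04d", seq_len(nF))
  ps <- PeakSet(observed, meta)

  truth <- structure(list(
    clean_matrix = clean, drift = driftApplied, drift_curves = curves,
    drift_kinds = kinds, batch_offsets = batchOffsets,
    group_effects = groupEff, qc_bias = exp(qcBias), config = cfg),
    class = "SyntheticTruth")
  list(matrix = ps, truth = truth)
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth:", nrow(x$clean_matrix), "observations x",
      ncol(x$clean_matrix), "features;",
      x$config$n_batches, "batches; drift kinds:",
      paste(unique(x$drift_kinds), collapse = "/"), "\n")
  invisible(x)
}
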