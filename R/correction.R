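# observation-index units for a spec: list of integer vectors (acquisition
# order), one per batch or a single global unit; conditioning injections are
# excluded (they are never fitted, rescaled against, nor corrected)
.fitUnits <- function(x, application) {
  idx <- .analysisIdx(x)
  if (application == "batchwise") {
    b <- batchId(x)[idx]
    lapply(unique(b), function(bb) idx[b == bb])
  } else {
    list(idx)
  }
}

# fit-subset mask within a unit
.scopeMask <- function(x, unit, scope) {
  if (scope == "qc_only") obsRole(x)[unit] == "QC"
  else rep(TRUE, length(unit))
}

#' Build correction factors for every observation and feature
#'
#' For each feature and each fit unit (batch, or the whole run), fits the
#' trend described by `spec` on the scope subset (QCs only, or all
#' observations) over acquisition rank and stores the trend value C at every
#' observation of the unit. Ranks are recomputed as consecutive integers
#' within the unit. Cells where the fitted trend is non-positive or
#' non-finite are flagged; a feature whose fit subset is entirely zero in a
#' unit is left uncorrected there (factors 1) and flagged, with one summary
#' warning.
#'
#' @param x a [PeakSet-class].
#' @param spec a [TrendSpec-class].
#' @param rescaleMode `"all_batches"` (default: R is the average of the scope
#'   subset over the whole run), `"first_batch"` (average of the scope subset
#'   of the first batch), or `"none"` (R = 1; corrected data are on a
#'   fold-of-trend scale).
#' @return a [CorrectionFactors-class].
#' @seealso [applyCorrection()], [rescaleFactor()]
#' @export
correctionFactors <- function(x, spec,
                              rescaleMode = c("all_batches", "first_batch",
                                              "none")) {
  stopifnot(is(x, "PeakSet"), is(spec, "TrendSpec"))
  validObject(spec)
  rescaleMode <- match.arg(rescaleMode)
  X <- intensityMatrix(x)
  nObs <- nrow(X); nFeat <- ncol(X)
  factors <- matrix(1, nObs, nFeat, dimnames = dimnames(X))
  flags <- matrix(0L, nObs, nFeat, dimnames = dimnames(X))
  units <- .fitUnits(x, spec@application)
  nAllZero <- 0L
  for (u in units) {
    ranks <- seq_along(u)
    mask <- .scopeMask(x, u, spec@scope)
    nFit <- sum(mask)
    if (nFit < .minFitPoints(spec)) {
      lab <- if (spec@application == "batchwise")
        paste("batch", batchId(x)[u[1]]) else "the full run"
      stop("insufficient fit points in ", lab, ": ", nFit, " ", spec@scope,
           " observation(s) for method '", spec@method, "' (needs >= ",
           .minFitPoints(spec), ")", call. = FALSE)
    }
    fitRanks <- ranks[mask]
    for (p in seq_len(nFeat)) {
      fv <- X[u[mask], p]
      if (all(fv == 0)) {
        nAllZero <- nAllZero + 1L
        flags[u, p] <- 2L
        next
      }
      fac <- .fitTrend(spec, fitRanks, fv, ranks)$factors
      bad <- !is.finite(fac)
      fac[bad] <- 0
      factors[u, p] <- fac
      flags[u, p][bad | fac <= 0] <- 1L
    }
  }
  if (nAllZero)
    warning(nAllZero, " feature/unit fit(s) were entirely zero; those ",
            "features are left uncorrected (factors 1) in those units",
            call. = FALSE)
  new("CorrectionFactors", factors = factors,
      rescale = rescaleFactor(x, spec, rescaleMode), spec = spec,
      rescaleMode = rescaleMode, flags = flags)
}

#' Per-feature rescaling factors
#'
#' The rescaling factor R restores corrected values (which are on a
#' fold-of-trend scale after division by C) to an interpretable intensity
#' level: the average of the scope subset (QCs, or all observations) of the
#' first batch, or of the whole run. The averaging measure follows
#' `spec@averaging` (mean by default).
#'
#' @inheritParams correctionFactors
#' @return numeric vector, one R per feature.
#' @export
rescaleFactor <- function(x, spec, rescaleMode = c("all_batches",
                                                   "first_batch", "none")) {
  stopifnot(is(x, "PeakSet"), is(spec, "TrendSpec"))
  rescaleMode <- match.arg(rescaleMode)
  nFeat <- nrow(x)
  if (rescaleMode == "none")
    return(stats::setNames(rep(1, nFeat), featureIds(x)))
  idx <- .analysisIdx(x)
  if (spec@scope == "qc_only") idx <- idx[isQC(x)[idx]]
  if (rescaleMode == "first_batch") {
    b1 <- min(batchId(x)[.analysisIdx(x)])
    idx <- idx[batchId(x)[idx] == b1]
    if (!length(idx))
      stop("rescale mode 'first_batch': no ", spec@scope,
           " observations in the first batch", call. = FALSE)
  }
  if (!length(idx))
    stop("rescaling: empty scope subset", call. = FALSE)
  m <- intensityMatrix(x)[idx, , drop = FALSE]
  r <- if (spec@averaging == "median") apply(m, 2, stats::median)
       else colMeans(m)
  stats::setNames(r, featureIds(x))
}

#' Apply a ratio correction
#'
#' Computes the corrected intensity `X' = X * R / C` cell by cell. Zeros
#' (non-detections) are never corrected into positive values. In `faithful`
#' mode the fitted factors are used as-is — dividing by a tiny positive trend
#' value reproduces the outlier blow-ups that a poorly fitting trend (e.g. a
#' QC regression line approaching zero) creates; such cells (|C| below
#' 1e-6 of the unit's median positive factor) are flagged. Cells with a
#' non-positive factor are set to 0 and flagged, keeping the corrected matrix
#' a valid non-negative `PeakSet`. In `clamp` mode tiny or non-positive
#' factors are replaced by the unit's median positive factor before division
#' and flagged as guarded; `faithful` and `clamp` differ only at flagged
#' cells.
#'
#' @param x the [PeakSet-class] to correct (the same object the factors were
#'   built from, or one with identical layout).
#' @param cf a [CorrectionFactors-class].
#' @param guard `"faithful"` (default) or `"clamp"`.
#' @return a corrected [PeakSet-class]; `metadata()$correction` carries the
#'   spec, guard, rescale mode and the per-cell application flags (0 ok,
#'   1 zeroed non-positive factor, 2 small divisor, 3 guarded).
#' @export
applyCorrection <- function(x, cf, guard = c("faithful", "clamp")) {
  stopifnot(is(x, "PeakSet"), is(cf, "CorrectionFactors"))
  guard <- match.arg(guard)
  X <- intensityMatrix(x)
  if (!identical(dim(X), dim(cf@factors)))
    stop("correction factors shape ", paste(dim(cf@factors), collapse = "x"),
         " does not match peak matrix ", paste(dim(X), collapse = "x"),
         call. = FALSE)
  C <- cf@factors
  R <- cf@rescale
  out <- X
  appliedFlags <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  units <- .fitUnits(x, cf@spec@application)
  for (u in units) {
    Cu <- C[u, , drop = FALSE]
    Xu <- X[u, , drop = FALSE]
    medPos <- apply(Cu, 2, function(v) {
      v <- v[is.finite(v) & v > 0]
      if (length(v)) stats::median(v) else NA_real_
    })
    thr <- 1e-6 * medPos
    for (p in seq_len(ncol(X))) {
      cvec <- Cu[, p]
      fl <- integer(length(cvec))
      if (guard == "clamp") {
        tiny <- !is.finite(cvec) | is.na(thr[p]) | cvec < thr[p]
        if (is.na(medPos[p])) {
          # no positive factor anywhere in the unit: leave uncorrectable
          # cells at zero
          cvec[tiny] <- Inf
        } else {
          cvec[tiny] <- medPos[p]
        }
        fl[tiny] <- 3L
      } else {
        nonpos <- !is.finite(cvec) | cvec <= 0
        small <- !nonpos & !is.na(thr[p]) & cvec < thr[p]
        cvec[nonpos] <- Inf            # X * R / Inf = 0, flagged
        fl[nonpos] <- 1L
        fl[small] <- 2L
      }
      res <- Xu[, p] * R[p] / cvec
      res[Xu[, p] == 0] <- 0
      out[u, p] <- res
      appliedFlags[u, p] <- fl
    }
  }
  y <- x
  a <- t(out)
  dimnames(a) <- dimnames(assay(y, "intensity"))
  assay(y, "intensity") <- a
  metadata(y)$correction <- list(spec = cf@spec, guard = guard,
                                 rescaleMode = cf@rescaleMode,
                                 flags = appliedFlags,
                                 n_flagged = sum(appliedFlags != 0L))
  validObject(y)
  y
}

#' One-call correction pipeline
#'
#' Convenience wrapper: `correctBatchDrift(x, spec)` is
#' `applyCorrection(x, correctionFactors(x, spec, rescaleMode), guard)`.
#' The default spec — a batch-wise background smoothing spline with
#' GCV-selected penalty, rescaled to the overall average — is the
#' best-performing strategy in the replicate-RSD sense.
#'
#' @inheritParams correctionFactors
#' @inheritParams applyCorrection
#' @return a corrected [PeakSet-class].
#' @examples
#' sim <- simulateDataset(simConfig(n_batches = 2, samples_per_batch = 12,
#'                                  n_features = 8, seed = 1))
#' corrected <- correctBatchDrift(sim$matrix, trendSpec("moving_median", w = 5))
#' @export
correctBatchDrift <- function(x, spec = trendSpec("spline"),
                              rescaleMode = "all_batches",
                              guard = c("faithful", "clamp")) {
  applyCorrection(x, correctionFactors(x, spec, rescaleMode),
                  match.arg(guard))
}
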