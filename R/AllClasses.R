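#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
#'   colData<- rowData
NULL

.OBS_ROLES <- c("QC", "experimental", "conditioning")
.TREND_METHODS <- c("constant", "linear", "moving_median", "polynomial",
                    "spline", "loess")

#' PeakSet: an ordered LC-MS peak-intensity matrix
#'
#' `PeakSet` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' single `"intensity"` assay (features in rows, observations in columns),
#' observation metadata in `colData()` and feature metadata in `rowData()`.
#' Observations are injections ordered by acquisition (`run_index`), grouped
#' into instrument batches, and carry a role: `"QC"` for pooled quality-control
#' injections, `"experimental"` for study samples, or `"conditioning"` for
#' column-conditioning injections that are excluded from every computation.
#'
#' Required `colData` columns: `sample_id`, `run_index`, `batch`, `role`.
#' Optional: `group` (experimental group label), `replicate_set` (id grouping
#' biological replicates of the same group and timepoint), `timepoint`.
#' Intensities are non-negative and finite; zero encodes "not detected".
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [PeakSet()] for construction, [readPeakTable()] for file input.
#' @export
setClass("PeakSet", contains = "SummarizedExperiment")

.validPeakSet <- function(object) {
  msg <- character()
  if (!("intensity" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'intensity' is required")
  cd <- colData(object)
  need <- c("sample_id", "run_index", "batch", "role")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste0("missing colData column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(cd$sample_id))
    msg <- c(msg, "sample_id values must be unique")
  ri <- cd$run_index
  if (anyNA(ri) || anyDuplicated(ri))
    msg <- c(msg, "run_index values must be non-missing and unique")
  if (is.unsorted(ri, strictly = TRUE))
    msg <- c(msg, "observations must be ordered by increasing run_index")
  if (!all(cd$role %in% .OBS_ROLES))
    msg <- c(msg, sprintf("role must be one of %s",
                          paste(.OBS_ROLES, collapse = "/")))
  if ("replicate_set" %in% colnames(cd)) {
    rs <- cd$replicate_set
    bad <- cd$role != "experimental" & !is.na(rs) & rs != ""
    if (any(bad))
      msg <- c(msg, "only experimental observations may carry a replicate_set")
    if ("group" %in% colnames(cd)) {
      for (s in unique(rs[!is.na(rs) & rs != ""])) {
        g <- unique(cd$group[!is.na(rs) & rs == s])
        if (length(g[!is.na(g)]) > 1)
          msg <- c(msg, sprintf("replicate_set '%s' spans several groups", s))
      }
    }
  }
  x <- assay(object, "intensity")
  if (length(x)) {
    if (!all(is.finite(x)))
      msg <- c(msg, "intensities must be finite (no NA/NaN/Inf)")
    else if (min(x) < 0)
      msg <- c(msg, "intensities must be non-negative")
  }
  fm <- rowData(object)
  if ("feature_id" %in% colnames(fm) && anyDuplicated(fm$feature_id))
    msg <- c(msg, "feature_id values must be unique")
  if (length(msg)) msg else TRUE
}
setValidity("PeakSet", .validPeakSet)

#' Construct a PeakSet
#'
#' @param intensity numeric matrix of non-negative intensities, observations in
#'   rows and features in columns (the usual wide-export orientation; it is
#'   transposed into the feature-by-observation assay internally). Row order
#'   need not follow acquisition order: observations are sorted by `run_index`.
#' @param observations `data.frame`/`DataFrame` of observation metadata, one
#'   row per intensity row, with at least `sample_id`, `run_index`, `batch`,
#'   `role`.
#' @param features optional `data.frame` of feature metadata with `feature_id`
#'   (defaults to the intensity column names) and optional `mz`, `rt` columns.
#'   `mz` outside \[80, 1000\] or `rt` outside \[1, 30\] minutes triggers an
#'   advisory warning only.
#' @return a validated [PeakSet-class] object ordered by `run_index`.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(NULL, c("F1", "F2")))
#' obs <- data.frame(sample_id = c("a", "b", "c"), run_index = 1:3,
#'                   batch = 1L, role = "experimental")
#' ps <- PeakSet(m, obs)
#' @export
PeakSet <- function(intensity, observations, features = NULL) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  observations <- as.data.frame(observations)
  if (nrow(intensity) != nrow(observations))
    stop("intensity rows (", nrow(intensity), ") and observation metadata rows (",
         nrow(observations), ") differ", call. = FALSE)
  if (is.null(features)) {
    ids <- colnames(intensity)
    if (is.null(ids)) ids <- sprintf("F%04d", seq_len(ncol(intensity)))
    features <- data.frame(feature_id = ids, stringsAsFactors = FALSE)
  }
  features <- as.data.frame(features)
  if (!"feature_id" %in% colnames(features))
    stop("feature metadata must contain a 'feature_id' column", call. = FALSE)
  if (nrow(features) != ncol(intensity))
    stop("feature metadata rows must match intensity columns", call. = FALSE)
  .checkFeatureBounds(features)
  observations$run_index <- as.integer(observations$run_index)
  observations$batch <- as.integer(observations$batch)
  ord <- order(observations$run_index)
  intensity <- intensity[ord, , drop = FALSE]
  observations <- observations[ord, , drop = FALSE]
  rownames(observations) <- NULL
  a <- t(intensity)
  dimnames(a) <- list(features$feature_id, observations$sample_id)
  se <- SummarizedExperiment(assays = list(intensity = a),
                             colData = DataFrame(observations),
                             rowData = DataFrame(features))
  new("PeakSet", se)
}

.checkFeatureBounds <- function(features) {
  if ("mz" %in% colnames(features)) {
    mz <- features$mz
    n <- sum(!is.na(mz) & (mz < 80 | mz > 1000))
    if (n) warning(n, " feature(s) have m/z outside the advisory range [80, 1000]",
                   call. = FALSE)
  }
  if ("rt" %in% colnames(features)) {
    rt <- features$rt
    n <- sum(!is.na(rt) & (rt < 1 | rt > 30))
    if (n) warning(n, " feature(s) have retention time outside the advisory range ",
                   "[1, 30] min", call. = FALSE)
  }
  invisible(NULL)
}

setMethod("show", "PeakSet", function(object) {
  cd <- colData(object)
  cat("PeakSet with", ncol(object), "observations x", nrow(object), "features\n")
  cat("  batches:", paste(unique(cd$batch), collapse = " "), "\n")
  cat("  roles:  ",
      paste(sprintf("%s=%d", names(table(cd$role)), table(cd$role)),
            collapse = " "), "\n")
  if ("group" %in% colnames(cd)) {
    g <- cd$group[cd$role == "experimental"]
    g <- g[!is.na(g)]
    if (length(g)) cat("  groups: ", paste(sort(unique(g)), collapse = " "), "\n")
  }
})

#' TrendSpec: a correction strategy
#'
#' Describes one run-order correction strategy: the trend model, its tuning
#' parameter, which observations the trend is fitted on (`scope`), and whether
#' it is fitted per batch or over the whole run (`application`).
#'
#' @slot method one of `"constant"`, `"linear"`, `"moving_median"`,
#'   `"polynomial"`, `"spline"`, `"loess"`.
#' @slot averaging `"mean"` or `"median"`; the averaging measure for the
#'   constant method, also used for rescaling factors.
#' @slot w integer half-width of the moving-median window (window size 2w+1).
#' @slot n integer polynomial degree.
#' @slot lambda positive smoothing-spline penalty, or `NA` for automatic
#'   selection by generalized cross-validation.
#' @slot alpha LOESS neighbourhood fraction in (0, 1].
#' @slot scope `"qc_only"` (trend from QCs, the classical QC correction) or
#'   `"background"` (trend from all observations including QCs).
#' @slot application `"batchwise"` (fit within each batch) or `"global"`.
#' @seealso [trendSpec()]
#' @export
setClass("TrendSpec", representation(
  method = "character", averaging = "character", w = "integer",
  n = "integer", lambda = "numeric", alpha = "numeric",
  scope = "character", application = "character"))

.validTrendSpec <- function(object) {
  msg <- character()
  if (!(object@method %in% .TREND_METHODS))
    msg <- c(msg, sprintf("method must be one of %s",
                          paste(.TREND_METHODS, collapse = "/")))
  if (!(object@averaging %in% c("mean", "median")))
    msg <- c(msg, "averaging must be 'mean' or 'median'")
  if (!(object@scope %in% c("qc_only", "background")))
    msg <- c(msg, "scope must be 'qc_only' or 'background'")
  if (!(object@application %in% c("batchwise", "global")))
    msg <- c(msg, "application must be 'batchwise' or 'global'")
  switch(object@method,
    moving_median = if (is.na(object@w) || object@w < 0L)
      msg <- c(msg, "moving_median requires window half-width w >= 0"),
    polynomial = if (is.na(object@n) || object@n < 1L)
      msg <- c(msg, "polynomial requires degree n >= 1"),
    spline = if (!is.na(object@lambda) && object@lambda <= 0)
      msg <- c(msg, "spline lambda must be positive (or NA for GCV)"),
    loess = if (is.na(object@alpha) || object@alpha <= 0 || object@alpha > 1)
      msg <- c(msg, "loess requires alpha in (0, 1]"))
  if (length(msg)) msg else TRUE
}
setValidity("TrendSpec", .validTrendSpec)

#' Create a trend specification
#'
#' @param method trend model; see [TrendSpec-class].
#' @param scope `"background"` (default: fit on all observations) or
#'   `"qc_only"`.
#' @param application `"batchwise"` (default) or `"global"`.
#' @param averaging `"mean"` (default) or `"median"`; used by the constant
#'   method and for rescaling factors.
#' @param w moving-median window half-width (window covers ranks i-w .. i+w).
#' @param n polynomial degree.
#' @param lambda smoothing-spline penalty; `"auto"` or `NA` (default) selects
#'   it by generalized cross-validation.
#' @param alpha LOESS neighbourhood fraction in (0, 1].
#' @return a validated [TrendSpec-class].
#' @examples
#' trendSpec("spline")                       # the default pipeline
#' trendSpec("moving_median", w = 5)
#' trendSpec("linear", scope = "qc_only")    # classical per-batch QC regression
#' @export
trendSpec <- function(method = c("spline", "constant", "linear", "moving_median",
                                 "polynomial", "loess"),
                      scope = c("background", "qc_only"),
                      application = c("batchwise", "global"),
                      averaging = c("mean", "median"),
                      w = NA, n = NA, lambda = NA, alpha = NA) {
  method <- match.arg(method)
  if (identical(lambda, "auto")) lambda <- NA_real_
  new("TrendSpec", method = method, averaging = match.arg(averaging),
      w = as.integer(w), n = as.integer(n), lambda = as.numeric(lambda),
      alpha = as.numeric(alpha), scope = match.arg(scope),
      application = match.arg(application))
}

setMethod("show", "TrendSpec", function(object) {
  par <- switch(object@method,
    constant = paste0("averaging=", object@averaging),
    moving_median = paste0("w=", object@w),
    polynomial = paste0("n=", object@n),
    spline = paste0("lambda=", if (is.na(object@lambda)) "auto" else
      format(object@lambda)),
    loess = paste0("alpha=", format(object@alpha)),
    "")
  cat("TrendSpec:", object@method,
      if (nzchar(par)) paste0("(", par, ")") else "",
      "| scope:", object@scope, "| application:", object@application, "\n")
})

#' Flat-list (de)serialization of a TrendSpec
#'
#' @param x a [TrendSpec-class] (for `trendSpecAsList`) or a named list with
#'   entries among `method, averaging, w, n, lambda, alpha, scope, application`
#'   (for `trendSpecFromList`).
#' @return a plain named list, or a `TrendSpec`.
#' @export
trendSpecAsList <- function(x) {
  stopifnot(is(x, "TrendSpec"))
  list(method = x@method, averaging = x@averaging, w = x@w, n = x@n,
       lambda = if (is.na(x@lambda)) "auto" else x@lambda, alpha = x@alpha,
       scope = x@scope, application = x@application)
}

#' @rdname trendSpecAsList
#' @export
trendSpecFromList <- function(x) {
  args <- x[!vapply(x, function(v) is.null(v) ||
                      (length(v) == 1 && is.na(v) && !is.character(v)), TRUE)]
  do.call(trendSpec, args)
}

#' CorrectionFactors: the realized trend for every cell
#'
#' Output of [correctionFactors()]: for each observation and feature the
#' correction factor C (the trend value at that acquisition rank), the
#' per-feature rescaling factor R, and per-cell flags recording where the
#' fitted trend was non-positive or degenerate.
#'
#' @slot factors numeric matrix (observations x features) of trend values C.
#' @slot rescale numeric per-feature rescaling factors R.
#' @slot spec the [TrendSpec-class] used.
#' @slot rescaleMode `"all_batches"`, `"first_batch"` or `"none"`.
#' @slot flags integer matrix matching `factors`: 0 = ok, 1 = non-positive or
#'   non-finite factor, 2 = fit subset entirely zero (feature left uncorrected
#'   in that unit, factors set to 1).
#' @export
setClass("CorrectionFactors", representation(
  factors = "matrix", rescale = "numeric", spec = "TrendSpec",
  rescaleMode = "character", flags = "matrix"))

.validCorrectionFactors <- function(object) {
  msg <- character()
  if (!identical(dim(object@factors), dim(object@flags)))
    msg <- c(msg, "factors and flags must have identical dimensions")
  if (length(object@rescale) != ncol(object@factors))
    msg <- c(msg, "rescale must have one value per feature")
  if (length(object@rescale) && !all(is.finite(object@rescale)))
    msg <- c(msg, "rescale factors must be finite")
  if (!(object@rescaleMode %in% c("all_batches", "first_batch", "none")))
    msg <- c(msg, "rescaleMode must be all_batches/first_batch/none")
  if (length(msg)) msg else TRUE
}
setValidity("CorrectionFactors", .validCorrectionFactors)

setMethod("show", "CorrectionFactors", function(object) {
  cat("CorrectionFactors:", nrow(object@factors), "observations x",
      ncol(object@factors), "features\n")
  show(object@spec)
  cat("  rescale mode:", object@rescaleMode, "\n")
  fl <- object@flags
  cat("  flagged cells:", sum(fl == 1L), "non-positive,", sum(fl == 2L),
      "all-zero fit\n")
})
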