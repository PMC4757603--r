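#' Remove features with zero medians
#'
#' Noise features near the limit of detection are removed before trend
#' estimation. Under `qc_median_nonzero` a feature is dropped when the median
#' of its QC intensities is zero, i.e. when half or more of the QCs record no
#' value — such features cannot support an accurate QC trend. Under
#' `overall_median_nonzero` (the background-correction counterpart) a feature
#' is dropped when the median over all analysis observations (experimental and
#' QC) is zero.
#'
#' With an even number of values and exactly half of them zero, the midpoint
#' median is positive and the feature is retained; these borderline features
#' are listed in the report.
#'
#' @param x a [PeakSet-class].
#' @param policy `"qc_median_nonzero"` or `"overall_median_nonzero"`.
#' @return the filtered [PeakSet-class]; the removal report (list with
#'   `policy`, `dropped_features`, `n_dropped`, `borderline_features`,
#'   `dropped_observations`) is stored in `metadata(x)$filter_report` and also
#'   attached to the return value.
#' @export
filterFeatures <- function(x, policy = c("qc_median_nonzero",
                                         "overall_median_nonzero")) {
  stopifnot(is(x, "PeakSet"))
  policy <- match.arg(policy)
  idx <- .analysisIdx(x)
  if (policy == "qc_median_nonzero") {
    idx <- idx[isQC(x)[idx]]
    if (!length(idx))
      stop("policy 'qc_median_nonzero' requires at least one QC observation",
           call. = FALSE)
  }
  m <- intensityMatrix(x)[idx, , drop = FALSE]
  med <- apply(m, 2, stats::median)
  drop <- med == 0
  nz <- colSums(m == 0)
  borderline <- nrow(m) %% 2 == 0 & nz == nrow(m) / 2
  out <- x[!drop, ]
  rep <- list(policy = policy,
              dropped_features = featureIds(x)[drop],
              n_dropped = sum(drop),
              borderline_features = featureIds(x)[borderline & !drop],
              dropped_observations = character())
  metadata(out)$filter_report <- rep
  out
}

#' Build the working set
#'
#' The baseline used for all performance assessment: the peak table after
#' manual removal of named outlier observations followed by zero-median
#' feature filtering. Outlier removal is deliberately manual (an explicit
#' `sample_id` list) — no automatic detection is attempted.
#'
#' @param x a [PeakSet-class].
#' @param policy feature-removal policy, see [filterFeatures()].
#' @param dropObservations character vector of `sample_id`s to remove before
#'   filtering (e.g. an inspected outlier).
#' @return the filtered [PeakSet-class] with the removal report in
#'   `metadata()$filter_report`.
#' @export
workingSet <- function(x, policy = c("overall_median_nonzero",
                                     "qc_median_nonzero"),
                       dropObservations = character()) {
  stopifnot(is(x, "PeakSet"))
  policy <- match.arg(policy)
  if (length(dropObservations)) {
    unknown <- setdiff(dropObservations, sampleIds(x))
    if (length(unknown))
      stop("unknown sample_id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    x <- x[, !(sampleIds(x) %in% dropObservations)]
  }
  out <- filterFeatures(x, policy)
  rep <- metadata(out)$filter_report
  rep$dropped_observations <- dropObservations
  metadata(out)$filter_report <- rep
  out
}

#' Serialize a removal report to JSON
#'
#' @param report a removal report from [filterFeatures()]/[workingSet()]
#'   (or a `PeakSet` carrying one in its metadata).
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
filterReportJson <- function(report, path = NULL) {
  if (is(report, "PeakSet")) report <- metadata(report)$filter_report
  stopifnot(is.list(report))
  js <- jsonlite::toJSON(list(policy = report$policy,
                              dropped_features = report$dropped_features,
                              dropped_observations = report$dropped_observations),
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
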