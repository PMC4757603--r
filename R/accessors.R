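#' PeakSet accessors
#'
#' Small accessors for the observation metadata and the intensity grid.
#' `intensityMatrix()` returns intensities in the analysis orientation used
#' throughout the package, observations (acquisition order) in rows and
#' features in columns; the underlying assay stores the transpose.
#'
#' @param x a [PeakSet-class].
#' @param value replacement intensity matrix, observations x features.
#' @return `intensityMatrix`: numeric matrix; the metadata accessors return
#'   one vector entry per observation (in acquisition order); `featureIds`
#'   returns the feature identifiers.
#' @name peakset-accessors
NULL

#' @rdname peakset-accessors
#' @export
intensityMatrix <- function(x) t(assay(x, "intensity"))

#' @rdname peakset-accessors
#' @export
`intensityMatrix<-` <- function(x, value) {
  stopifnot(identical(dim(value), c(ncol(x), nrow(x))))
  a <- t(value)
  dimnames(a) <- dimnames(assay(x, "intensity"))
  assay(x, "intensity") <- a
  validObject(x)
  x
}

#' @rdname peakset-accessors
#' @export
sampleIds <- function(x) as.character(colData(x)$sample_id)

#' @rdname peakset-accessors
#' @export
runIndex <- function(x) as.integer(colData(x)$run_index)

#' @rdname peakset-accessors
#' @export
batchId <- function(x) as.integer(colData(x)$batch)

#' @rdname peakset-accessors
#' @export
obsRole <- function(x) as.character(colData(x)$role)

#' @rdname peakset-accessors
#' @export
obsGroup <- function(x) {
  cd <- colData(x)
  if ("group" %in% colnames(cd)) as.character(cd$group)
  else rep(NA_character_, ncol(x))
}

#' @rdname peakset-accessors
#' @export
replicateSet <- function(x) {
  cd <- colData(x)
  if ("replicate_set" %in% colnames(cd)) {
    rs <- as.character(cd$replicate_set)
    rs[!is.na(rs) & rs == ""] <- NA_character_
    rs
  } else rep(NA_character_, ncol(x))
}

#' @rdname peakset-accessors
#' @export
isQC <- function(x) obsRole(x) == "QC"

#' @rdname peakset-accessors
#' @export
featureIds <- function(x) as.character(rowData(x)$feature_id)

# observation indices eligible for analysis (conditioning injections excluded)
.analysisIdx <- function(x) which(obsRole(x) != "conditioning")

# subset a PeakSet to a set of observation indices, keeping order
.subsetObs <- function(x, idx) {
  x[, sort(idx)]
}
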