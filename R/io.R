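.META_COLS <- c("sample_id", "run_index", "batch", "role", "group",
                "replicate_set", "timepoint")
.REQ_META <- c("sample_id", "run_index", "batch", "role")

.readDelim <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "",
                    na.strings = c("NA", ""))
}

#' Read a peak table from delimited text
#'
#' Reads a Progenesis-style wide intensity export (first column `sample_id`,
#' one column per feature) plus an observation-metadata file, and returns a
#' validated [PeakSet-class] ordered by `run_index`. The delimiter is chosen
#' by extension: tab for `.tsv`/`.txt`, comma otherwise.
#'
#' Empty intensity cells are read as 0 ("no value"); their count is reported
#' via `message()`. Negative or unparseable cells are an error naming the
#' offending observation and feature. A single-file layout is also accepted:
#' if `metadataPath` is `NULL`, columns of the intensity file named after the
#' reserved metadata columns (`sample_id`, `run_index`, `batch`, `role`,
#' `group`, `replicate_set`, `timepoint`) are split off as metadata.
#'
#' @param intensityPath path to the intensity table.
#' @param metadataPath path to the observation metadata table, or `NULL` for
#'   the single-file layout.
#' @return a [PeakSet-class].
#' @seealso [writePeakTable()], its inverse.
#' @export
readPeakTable <- function(intensityPath, metadataPath = NULL) {
  tab <- .readDelim(intensityPath)
  if (!"sample_id" %in% colnames(tab))
    stop("intensity file must have a 'sample_id' first column", call. = FALSE)
  if (is.null(metadataPath)) {
    metaCols <- intersect(.META_COLS, colnames(tab))
    miss <- setdiff(.REQ_META, metaCols)
    if (length(miss))
      stop("single-file layout is missing required metadata column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    meta <- tab[, metaCols, drop = FALSE]
    tab <- tab[, c("sample_id", setdiff(colnames(tab), metaCols)),
               drop = FALSE]
  } else {
    meta <- .readDelim(metadataPath)
    miss <- setdiff(.REQ_META, colnames(meta))
    if (length(miss))
      stop("metadata file is missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    only_i <- setdiff(tab$sample_id, meta$sample_id)
    only_m <- setdiff(meta$sample_id, tab$sample_id)
    if (length(only_i) || length(only_m))
      stop("sample_id mismatch between intensity and metadata files; ",
           "intensity-only: [", paste(only_i, collapse = ", "),
           "], metadata-only: [", paste(only_m, collapse = ", "), "]",
           call. = FALSE)
  }
  featCols <- setdiff(colnames(tab), "sample_id")
  m <- as.matrix(tab[, featCols, drop = FALSE])
  if (is.character(m)) {
    suppressWarnings(storage.mode(m) <- "double")
  }
  nEmpty <- sum(is.na(m))
  # NA from na.strings ("", "NA") is an empty cell -> 0; anything else that
  # failed numeric coercion is unparseable
  raw <- as.matrix(tab[, featCols, drop = FALSE])
  unparse <- which(is.na(m) & !is.na(raw) & raw != "", arr.ind = TRUE)
  if (nrow(unparse))
    stop("unparseable intensity at observation '",
         tab$sample_id[unparse[1, 1]], "', feature '",
         featCols[unparse[1, 2]], "'", call. = FALSE)
  if (nEmpty)
    message(nEmpty, " empty intensity cell(s) read as 0")
  m[is.na(m)] <- 0
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative intensity at observation '", tab$sample_id[neg[1, 1]],
         "', feature '", featCols[neg[1, 2]], "'", call. = FALSE)
  # align metadata rows to intensity rows
  meta <- meta[match(tab$sample_id, meta$sample_id), , drop = FALSE]
  rownames(m) <- NULL
  colnames(m) <- featCols
  PeakSet(m, meta)
}

#' Write a PeakSet to delimited text
#'
#' Writes `<outPrefix>_intensities.csv` (first column `sample_id`, one column
#' per feature, values at full precision so that [readPeakTable()] reproduces
#' the matrix exactly) and `<outPrefix>_metadata.csv`.
#'
#' @param x a [PeakSet-class].
#' @param outPrefix output path prefix.
#' @return invisibly, a character vector of the two file paths.
#' @export
writePeakTable <- function(x, outPrefix) {
  stopifnot(is(x, "PeakSet"))
  m <- intensityMatrix(x)
  num <- matrix(vapply(m, function(v) sprintf("%.17g", v), character(1)),
                nrow = nrow(m))
  df <- data.frame(sample_id = sampleIds(x), num, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", featureIds(x))
  pInt <- paste0(outPrefix, "_intensities.csv")
  pMeta <- paste0(outPrefix, "_metadata.csv")
  ok <- tryCatch({
    utils::write.csv(df, pInt, row.names = FALSE, quote = TRUE)
    meta <- as.data.frame(colData(x))
    utils::write.csv(meta[, intersect(.META_COLS, colnames(meta)),
                          drop = FALSE],
                     pMeta, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write peak table: ", conditionMessage(ok), call. = FALSE)
  invisible(c(intensities = pInt, metadata = pMeta))
}

#' Report on acquisition layout
#'
#' Advisory summary of the batch/QC layout: per-batch counts of QC and
#' experimental observations, the maximal number of consecutive experimental
#' injections not covered by a QC on either side (counting the stretches
#' before the first and after the last QC of the batch), batches without QCs,
#' and replicate sets with fewer than three members (which the replicate-RSD
#' assessment will exclude). Never modifies the object.
#'
#' @param x a [PeakSet-class].
#' @return a list with elements `batches` (data.frame: `batch`, `n_qc`,
#'   `n_experimental`, `max_qc_gap`), `no_qc_batches` (integer vector) and
#'   `small_replicate_sets` (data.frame: `replicate_set`, `size`).
#' @export
validateLayout <- function(x) {
  stopifnot(is(x, "PeakSet"))
  idx <- .analysisIdx(x)
  batch <- batchId(x)[idx]
  role <- obsRole(x)[idx]
  ub <- unique(batch)
  rows <- lapply(ub, function(b) {
    r <- role[batch == b]
    qcPos <- which(r == "QC")
    gaps <- diff(c(0L, qcPos, length(r) + 1L)) - 1L
    data.frame(batch = b, n_qc = sum(r == "QC"),
               n_experimental = sum(r == "experimental"),
               max_qc_gap = if (length(qcPos)) max(gaps) else sum(r == "experimental"))
  })
  batches <- do.call(rbind, rows)
  rs <- replicateSet(x)
  rs <- rs[!is.na(rs)]
  sizes <- table(rs)
  small <- sizes[sizes < 3]
  list(batches = batches,
       no_qc_batches = batches$batch[batches$n_qc == 0],
       small_replicate_sets = data.frame(
         replicate_set = names(small), size = as.integer(small),
         stringsAsFactors = FALSE, row.names = NULL))
}
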