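#' Label a correction strategy
#'
#' @param spec a [TrendSpec-class].
#' @return short human-readable label, e.g. `"batchwise background spline"`.
#' @export
strategyLabel <- function(spec) {
  scope <- if (spec@scope == "qc_only") "QC-only" else "background"
  par <- switch(spec@method,
    constant = spec@averaging,
    moving_median = paste0("w=", spec@w),
    polynomial = paste0("n=", spec@n),
    spline = if (is.na(spec@lambda)) "GCV" else paste0("lambda=",
                                                       format(spec@lambda)),
    loess = paste0("alpha=", format(spec@alpha)),
    NULL)
  paste0(spec@application, " ", scope, " ", spec@method,
         if (!is.null(par)) paste0(" (", par, ")") else "")
}

#' Benchmark correction strategies
#'
#' Runs every strategy on the supplied (already filtered) working set and
#' tabulates, for the uncorrected baseline and each corrected matrix, the
#' mean replicate RSD, its reduction versus the baseline in percentage
#' points, and the PCA-MANOVA F and p for each requested comparison. The
#' table is sorted by mean RSD. A strategy whose estimation fails is
#' recorded with its error message and skipped from the metric columns. The
#' whole report is deterministic for a fixed matrix and strategy list.
#'
#' @param x the working-set [PeakSet-class].
#' @param strategies list of [TrendSpec-class] objects, or of lists
#'   `list(spec =, rescaleMode =, guard =)`; names become row labels
#'   (defaults to [strategyLabel()]).
#' @param comparisons list of comparisons: a character vector of two or more
#'   group labels tests those experimental groups; the string `"batch"` tests
#'   batch separation. Default: batch separation only.
#' @param nComponents principal components scored in each PCA-MANOVA test.
#' @return list with `table` (one row per strategy plus the uncorrected
#'   baseline) and `corrected` (named list of corrected `PeakSet`s).
#' @export
runBenchmark <- function(x, strategies = list(),
                         comparisons = list("batch"), nComponents = 2) {
  stopifnot(is(x, "PeakSet"))
  if (length(strategies) && is.null(names(strategies)))
    names(strategies) <- vapply(strategies, function(s) {
      if (is(s, "TrendSpec")) strategyLabel(s) else strategyLabel(s$spec)
    }, character(1))

  cmpName <- vapply(comparisons, function(cc)
    if (identical(cc, "batch")) "batch" else paste(cc, collapse = "_vs_"),
    character(1))
  fCols <- paste0("F_", cmpName, recycle0 = TRUE)
  pCols <- paste0("p_", cmpName, recycle0 = TRUE)

  evalOne <- function(mat) {
    rsd <- replicateRsd(mat, original = x)
    stats <- lapply(comparisons, function(cc) {
      pm <- tryCatch({
        if (identical(cc, "batch"))
          suppressMessages(pcaManova(mat, "batch", nComponents = nComponents))
        else
          suppressMessages(pcaManova(mat, "group", groups = cc,
                                     nComponents = nComponents))
      }, error = function(e) NULL)
      if (is.null(pm)) c(NA_real_, NA_real_) else c(pm$f_stat, pm$p_value)
    })
    c(list(mean_rsd_percent = rsd$mean_rsd_percent),
      stats::setNames(lapply(stats, `[`, 1), fCols),
      stats::setNames(lapply(stats, `[`, 2), pCols))
  }

  baseline <- evalOne(x)
  corrected <- list()
  rows <- list()
  asRow <- function(strategy, met, reduction, err = NA_character_) {
    row <- data.frame(strategy = strategy,
                      mean_rsd_percent = met$mean_rsd_percent,
                      rsd_reduction_pp = reduction,
                      stringsAsFactors = FALSE)
    if (length(met) > 1) row <- cbind(row, as.data.frame(met[-1]))
    row$error <- err
    row
  }
  rows[["working set (uncorrected)"]] <-
    asRow("working set (uncorrected)", baseline, 0)
  for (nm in names(strategies)) {
    s <- strategies[[nm]]
    spec <- if (is(s, "TrendSpec")) s else s$spec
    rescaleMode <- if (is.list(s) && !is.null(s$rescaleMode)) s$rescaleMode
                   else "all_batches"
    guard <- if (is.list(s) && !is.null(s$guard)) s$guard else "faithful"
    res <- tryCatch({
      mat <- suppressWarnings(applyCorrection(
        x, correctionFactors(x, spec, rescaleMode), guard))
      met <- evalOne(mat)
      list(mat = mat,
           row = asRow(nm, met,
                       baseline$mean_rsd_percent - met$mean_rsd_percent))
    }, error = function(e) {
      met <- c(list(mean_rsd_percent = NA_real_),
               stats::setNames(as.list(rep(NA_real_, length(fCols))), fCols),
               stats::setNames(as.list(rep(NA_real_, length(pCols))), pCols))
      list(mat = NULL,
           row = asRow(nm, met, NA_real_, err = conditionMessage(e)))
    })
    if (!is.null(res$mat)) corrected[[nm]] <- res$mat
    rows[[nm]] <- res$row
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- tab[order(is.na(tab$mean_rsd_percent), tab$mean_rsd_percent), ]
  rownames(tab) <- NULL
  list(table = tab, corrected = corrected)
}
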