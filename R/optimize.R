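.tunableParam <- function(spec) {
  switch(spec@method,
    moving_median = "w", polynomial = "n", spline = "lambda",
    loess = "alpha",
    stop("method '", spec@method, "' has no tunable smoothing parameter",
         call. = FALSE))
}

.withParam <- function(spec, value) {
  slot(spec, .tunableParam(spec)) <-
    if (.tunableParam(spec) %in% c("w", "n")) as.integer(value)
    else as.numeric(value)
  validObject(spec)
  spec
}

#' Default parameter grids
#'
#' Window half-widths 1..15 for the moving median, degrees 1..8 for the
#' polynomial, neighbourhood fractions 0.05..1 (step 0.05) for LOESS. The
#' smoothing-spline penalty is not gridded here: it is selected internally by
#' generalized cross-validation (`lambda = "auto"`).
#'
#' @param method trend method name.
#' @return numeric vector of candidate parameter values.
#' @export
defaultGrid <- function(method = c("moving_median", "polynomial", "loess")) {
  switch(match.arg(method),
    moving_median = 1:15,
    polynomial = 1:8,
    loess = seq(0.05, 1, by = 0.05))
}

#' Optimize a smoother parameter by mean replicate RSD
#'
#' Evaluates every candidate parameter value of `grid`: builds the correction
#' for `specTemplate` with that value, applies it, and computes the mean
#' replicate RSD; returns the value minimizing it together with the full
#' table. The procedure is fully deterministic for a given matrix and grid.
#' Candidates whose estimation fails are recorded with the reason and
#' excluded from the argmin. Ties (mean RSD equal to within 1e-12) break
#' toward the smoother/simpler model: the smaller window or degree, the
#' larger LOESS neighbourhood.
#'
#' @param x the [PeakSet-class] to optimize on (typically the working set).
#' @param specTemplate a [TrendSpec-class]; its tunable parameter (w, n or
#'   alpha by method) is replaced by each grid value.
#' @param grid candidate parameter values; defaults to [defaultGrid()] for
#'   the template's method.
#' @param rescaleMode,guard passed to [correctionFactors()] /
#'   [applyCorrection()].
#' @param grandMean passed to [replicateRsd()].
#' @return list with `best` (the chosen value), `best_spec` (the template
#'   with it filled in), `best_mean_rsd_percent`, and `table` (data.frame:
#'   `value`, `mean_rsd_percent`, `failed`, `reason`).
#' @examples
#' sim <- simulateDataset(simConfig(n_batches = 2, samples_per_batch = 18,
#'                                  n_features = 15, seed = 3))
#' opt <- gridOptimize(sim$matrix, trendSpec("moving_median", w = 1),
#'                     grid = c(1, 3, 5))
#' opt$best
#' @export
gridOptimize <- function(x, specTemplate, grid = NULL,
                         rescaleMode = "all_batches",
                         guard = c("faithful", "clamp"),
                         grandMean = c("experimental", "sets")) {
  stopifnot(is(x, "PeakSet"), is(specTemplate, "TrendSpec"))
  guard <- match.arg(guard)
  grandMean <- match.arg(grandMean)
  par <- .tunableParam(specTemplate)
  if (is.null(grid)) grid <- defaultGrid(specTemplate@method)
  if (!length(grid)) stop("parameter grid is empty", call. = FALSE)
  rows <- lapply(grid, function(v) {
    res <- tryCatch({
      spec <- .withParam(specTemplate, v)
      corrected <- suppressWarnings(
        applyCorrection(x, correctionFactors(x, spec, rescaleMode), guard))
      rsd <- replicateRsd(corrected, original = x, grandMean = grandMean)
      data.frame(value = v, mean_rsd_percent = rsd$mean_rsd_percent,
                 failed = FALSE, reason = NA_character_)
    }, error = function(e)
      data.frame(value = v, mean_rsd_percent = NA_real_, failed = TRUE,
                 reason = conditionMessage(e)))
    res
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$failed
  if (!any(ok))
    stop("every grid candidate failed; first reason: ", tab$reason[1],
         call. = FALSE)
  best_rsd <- min(tab$mean_rsd_percent[ok])
  tied <- which(ok & tab$mean_rsd_percent <= best_rsd + 1e-12)
  best <- if (par == "alpha") max(tab$value[tied]) else min(tab$value[tied])
  list(best = best, best_spec = .withParam(specTemplate, best),
       best_mean_rsd_percent =
         tab$mean_rsd_percent[ok & tab$value == best][1],
       table = tab)
}
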