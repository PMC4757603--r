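#' Trend fits over acquisition rank
#'
#' Each trend estimator fits a per-feature intensity trend over acquisition
#' rank from a subset of observations (the fit subset: QCs only, or all
#' observations for background correction) and evaluates it at every rank of
#' the fit unit (a batch, or the whole run). Ranks are consecutive integers
#' `1..m` within the unit, recomputed after any observation removal, so that
#' rank `i` counts acquired injections rather than raw run indices.
#'
#' All estimators return a `TrendFit`: a list with `factors` (the trend value
#' at each `evalRanks` position — the correction factors C), `fitPoints`
#' (data.frame of the `(rank, value)` pairs used) and method-specific
#' `diagnostics`. Factors are finite at every evaluated rank, including ranks
#' outside the fit subset's span (regression and smoother fits extrapolate by
#' their own model; the moving median extrapolates its edge value).
#'
#' @param fitRanks integer ranks of the fit subset within the unit.
#' @param fitValues intensities at `fitRanks`.
#' @param evalRanks ranks at which the trend is evaluated (default: the unit's
#'   full rank sequence is whatever you pass; typically `1..m`).
#' @param averaging `"mean"` or `"median"` (constant trend).
#' @param w window half-width `>= 0`: the window at rank `i` covers fit points
#'   with ranks in `[i - w, i + w]`, truncated at the unit edges; `w = 0`
#'   reproduces the fit values at fit ranks.
#' @param degree polynomial degree `n` (must be `< length(fitRanks)`).
#' @param lambda positive smoothing penalty, or `"auto"`/`NA` for selection by
#'   generalized cross-validation (the default used throughout). A penalty
#'   beyond the solver's range returns the exact infinite-smoothing limit,
#'   the least-squares line (`diagnostics$saturated = TRUE`).
#' @param alpha LOESS neighbourhood fraction in (0, 1]; the local fit at each
#'   rank uses the `q = ceiling(alpha * m)` nearest fit points with tricube
#'   weights on distance scaled by the neighbourhood radius.
#' @return a `TrendFit` list (class `"TrendFit"`).
#' @name trend-fits
#' @examples
#' f <- linearTrend(c(2, 5, 8), c(5, 11, 17), 1:9)   # points on 2i + 1
#' f$factors                                          # 3 5 7 ... 19
NULL

.newTrendFit <- function(factors, fitRanks, fitValues, diagnostics = list()) {
  structure(list(factors = as.numeric(factors),
                 fitPoints = data.frame(rank = fitRanks, value = fitValues),
                 diagnostics = diagnostics),
            class = "TrendFit")
}

#' @export
print.TrendFit <- function(x, ...) {
  cat("TrendFit:", length(x$factors), "factors from", nrow(x$fitPoints),
      "fit points\n")
  invisible(x)
}

.checkFitInput <- function(fitRanks, fitValues, evalRanks, minPoints = 1) {
  if (length(fitRanks) != length(fitValues))
    stop("fitRanks and fitValues lengths differ", call. = FALSE)
  if (length(fitRanks) < minPoints)
    stop("trend estimation needs at least ", minPoints,
         " fit point(s), got ", length(fitRanks), call. = FALSE)
  if (!all(is.finite(fitValues)) || !all(is.finite(evalRanks)))
    stop("non-finite values in trend fit input", call. = FALSE)
  invisible(NULL)
}

#' @rdname trend-fits
#' @export
constantTrend <- function(fitRanks, fitValues, evalRanks = fitRanks,
                          averaging = c("mean", "median")) {
  averaging <- match.arg(averaging)
  .checkFitInput(fitRanks, fitValues, evalRanks, 1)
  a <- if (averaging == "mean") mean(fitValues) else stats::median(fitValues)
  .newTrendFit(rep(a, length(evalRanks)), fitRanks, fitValues,
               list(average = a, averaging = averaging))
}

#' @rdname trend-fits
#' @export
linearTrend <- function(fitRanks, fitValues, evalRanks = fitRanks) {
  .checkFitInput(fitRanks, fitValues, evalRanks, 2)
  if (length(unique(fitRanks)) < 2)
    stop("linear trend needs at least two distinct fit ranks", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, fitRanks), fitValues)
  co <- fit$coefficients
  .newTrendFit(co[1] + co[2] * evalRanks, fitRanks, fitValues,
               list(intercept = unname(co[1]), slope = unname(co[2])))
}

#' @rdname trend-fits
#' @export
movingMedianTrend <- function(fitRanks, fitValues, evalRanks = fitRanks, w) {
  .checkFitInput(fitRanks, fitValues, evalRanks, 1)
  w <- as.integer(w)
  if (is.na(w) || w < 0)
    stop("moving-median window half-width w must be >= 0", call. = FALSE)
  atFit <- vapply(fitRanks, function(r) {
    stats::median(fitValues[fitRanks >= r - w & fitRanks <= r + w])
  }, numeric(1))
  factors <- if (length(fitRanks) == 1L) {
    rep(atFit, length(evalRanks))
  } else {
    ord <- order(fitRanks)
    stats::approx(fitRanks[ord], atFit[ord], xout = evalRanks, rule = 2,
                  ties = "ordered")$y
  }
  .newTrendFit(factors, fitRanks, fitValues, list(w = w))
}

#' @rdname trend-fits
#' @export
polynomialTrend <- function(fitRanks, fitValues, evalRanks = fitRanks, degree) {
  degree <- as.integer(degree)
  if (is.na(degree) || degree < 1)
    stop("polynomial degree must be >= 1", call. = FALSE)
  .checkFitInput(fitRanks, fitValues, evalRanks, 1)
  if (length(unique(fitRanks)) <= degree)
    stop("polynomial of degree ", degree, " is underdetermined by ",
         length(unique(fitRanks)), " distinct fit ranks", call. = FALSE)
  # rescale ranks to [-1, 1] for conditioning of the Vandermonde basis
  ctr <- mean(range(fitRanks))
  hw <- max(diff(range(fitRanks)) / 2, 1)
  basis <- function(r) outer((r - ctr) / hw, 0:degree, `^`)
  fit <- stats::lm.fit(basis(fitRanks), fitValues)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  .newTrendFit(drop(basis(evalRanks) %*% co), fitRanks, fitValues,
               list(degree = degree, coefficients = unname(co),
                    center = ctr, halfwidth = hw))
}

#' @rdname trend-fits
#' @export
splineTrend <- function(fitRanks, fitValues, evalRanks = fitRanks,
                        lambda = "auto") {
  .checkFitInput(fitRanks, fitValues, evalRanks, 4)
  if (length(unique(fitRanks)) < 4)
    stop("smoothing spline needs at least four distinct fit ranks",
         call. = FALSE)
  if (identical(lambda, "auto")) lambda <- NA_real_
  lambda <- as.numeric(lambda)
  if (!is.na(lambda) && lambda <= 0)
    stop("spline lambda must be positive", call. = FALSE)
  fit <- tryCatch({
    if (is.na(lambda))
      stats::smooth.spline(fitRanks, fitValues, cv = FALSE, keep.data = FALSE,
                           all.knots = TRUE)
    else
      stats::smooth.spline(fitRanks, fitValues, lambda = lambda,
                           keep.data = FALSE, all.knots = TRUE)
  }, error = function(e) {
    # beyond the solver's lambda range the spline has converged to its
    # infinite-smoothing limit, the least-squares line
    if (!is.na(lambda) && lambda > 1 &&
        grepl("too extreme", conditionMessage(e))) return(NULL)
    stop("smoothing-spline fit failed: ", conditionMessage(e), call. = FALSE)
  })
  if (is.null(fit)) {
    lin <- linearTrend(fitRanks, fitValues, evalRanks)
    lin$diagnostics <- c(lin$diagnostics,
                         list(lambda = lambda, saturated = TRUE))
    return(lin)
  }
  .newTrendFit(stats::predict(fit, as.numeric(evalRanks))$y,
               fitRanks, fitValues,
               list(lambda = fit$lambda, gcv = fit$cv.crit,
                    df = fit$df, auto = is.na(lambda)))
}

# tricube-weighted local linear regression at a single point
.loessPoint <- function(x0, fitRanks, fitValues, q) {
  d <- abs(fitRanks - x0)
  dq <- sort(d, partial = q)[q]
  if (dq <= 0) dq <- 1e-12
  u <- pmin(d / dq, 1)
  wts <- (1 - u^3)^3
  if (sum(wts > 0) < 2) {
    # degenerate neighbourhood (all weight on one point): widen slightly so
    # the q nearest points all carry positive weight
    u <- pmin(d / (dq * (1 + 1e-9)), 1)
    wts <- (1 - u^3)^3
    wts[d <= dq & wts <= 0] <- 1e-9
  }
  X <- cbind(1, fitRanks - x0)
  fit <- stats::lm.wfit(X, fitValues, wts)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  co[1]
}

#' @rdname trend-fits
#' @export
loessTrend <- function(fitRanks, fitValues, evalRanks = fitRanks, alpha) {
  .checkFitInput(fitRanks, fitValues, evalRanks, 2)
  alpha <- as.numeric(alpha)
  if (is.na(alpha) || alpha <= 0 || alpha > 1)
    stop("loess alpha must be in (0, 1]", call. = FALSE)
  m <- length(fitRanks)
  q <- ceiling(alpha * m)
  if (q < 2)
    stop("loess neighbourhood ceiling(alpha * m) = ", q,
         " is smaller than 2 points", call. = FALSE)
  factors <- vapply(as.numeric(evalRanks), .loessPoint, numeric(1),
                    fitRanks = as.numeric(fitRanks),
                    fitValues = as.numeric(fitValues), q = q)
  .newTrendFit(factors, fitRanks, fitValues, list(alpha = alpha, q = q))
}

# dispatch a TrendSpec to its estimator
.fitTrend <- function(spec, fitRanks, fitValues, evalRanks) {
  switch(spec@method,
    constant = constantTrend(fitRanks, fitValues, evalRanks, spec@averaging),
    linear = linearTrend(fitRanks, fitValues, evalRanks),
    moving_median = movingMedianTrend(fitRanks, fitValues, evalRanks, spec@w),
    polynomial = polynomialTrend(fitRanks, fitValues, evalRanks, spec@n),
    spline = splineTrend(fitRanks, fitValues, evalRanks,
                         if (is.na(spec@lambda)) "auto" else spec@lambda),
    loess = loessTrend(fitRanks, fitValues, evalRanks, spec@alpha))
}

# minimum number of fit points each method needs
.minFitPoints <- function(spec) {
  switch(spec@method,
    constant = 1L, linear = 2L, moving_median = 1L,
    polynomial = spec@n + 1L, spline = 4L,
    loess = max(2L, as.integer(floor(1 / spec@alpha)) + 1L))
}
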