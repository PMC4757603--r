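#' Mean relative standard deviation of biological replicates
#'
#' The primary performance measure for a correction: for every (feature,
#' replicate set) pair the RSD is the sample standard deviation of the set's
#' intensities divided by the feature's grand mean, and `mean_rsd` averages
#' the included pairs. Only replicate sets with at least three members are
#' used; a pair is excluded when any of the set's values is zero in the
#' original (pre-correction) data, when all of its corrected values are zero,
#' or when the grand mean is zero. Lower mean RSD means replicate samples of
#' the same biological condition agree better after correction.
#'
#' @param x the [PeakSet-class] to evaluate (corrected or not).
#' @param original the pre-correction [PeakSet-class] used for the
#'   zero-in-original exclusion rule; defaults to `x` itself (evaluating
#'   uncorrected data). Must share `x`'s observations and features.
#' @param grandMean `"experimental"` (default: the feature mean over all
#'   experimental observations) or `"sets"` (mean over the members of
#'   eligible replicate sets only).
#' @return an `RsdReport` (S3 list): `entries` data.frame with columns
#'   `feature_id`, `replicate_set`, `sd`, `grand_mean`, `rsd`, `excluded`
#'   (`NA` or one of `set_too_small`, `zero_in_original`,
#'   `all_zero_corrected`, `zero_grand_mean`); `mean_rsd` (fraction);
#'   `mean_rsd_percent`; `n_included`.
#' @export
replicateRsd <- function(x, original = NULL,
                         grandMean = c("experimental", "sets")) {
  stopifnot(is(x, "PeakSet"))
  grandMean <- match.arg(grandMean)
  if (is.null(original)) original <- x
  stopifnot(is(original, "PeakSet"))
  if (!identical(dim(x), dim(original)) ||
      !identical(sampleIds(x), sampleIds(original)))
    stop("'original' must share the observations and features of 'x'",
         call. = FALSE)
  rs <- replicateSet(x)
  expIdx <- which(obsRole(x) == "experimental")
  sets <- rs[expIdx]
  if (all(is.na(sets)))
    stop("no replicate_set labels: cannot compute replicate RSD",
         call. = FALSE)
  X <- intensityMatrix(x)
  O <- intensityMatrix(original)
  fid <- featureIds(x)
  setIds <- sort(unique(sets[!is.na(sets)]))
  sizes <- vapply(setIds, function(s) sum(sets == s, na.rm = TRUE), 0L)
  eligible <- setIds[sizes >= 3]
  gm <- if (grandMean == "experimental") {
    colMeans(X[expIdx, , drop = FALSE])
  } else {
    inSet <- expIdx[!is.na(sets) & sets %in% eligible]
    if (!length(inSet))
      stop("no eligible replicate sets (need >= 3 members)", call. = FALSE)
    colMeans(X[inSet, , drop = FALSE])
  }
  pieces <- lapply(setIds, function(s) {
    idx <- expIdx[!is.na(sets) & sets == s]
    k <- length(idx)
    nFeat <- length(fid)
    if (k < 3) {
      return(data.frame(feature_id = fid, replicate_set = s, sd = NA_real_,
                        grand_mean = gm, rsd = NA_real_,
                        excluded = "set_too_small",
                        stringsAsFactors = FALSE))
    }
    m <- X[idx, , drop = FALSE]
    mo <- O[idx, , drop = FALSE]
    mu <- colMeans(m)
    sdv <- sqrt(colSums((m - rep(mu, each = k))^2) / (k - 1))
    excl <- rep(NA_character_, nFeat)
    excl[gm == 0] <- "zero_grand_mean"
    excl[colSums(m == 0) == k] <- "all_zero_corrected"
    excl[colSums(mo == 0) > 0] <- "zero_in_original"
    rsd <- ifelse(is.na(excl), sdv / gm, NA_real_)
    data.frame(feature_id = fid, replicate_set = s, sd = sdv,
               grand_mean = gm, rsd = rsd, excluded = excl,
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, pieces)
  rownames(entries) <- NULL
  inc <- is.na(entries$excluded)
  if (!any(inc))
    stop("no eligible (feature, replicate set) pairs for RSD evaluation",
         call. = FALSE)
  structure(list(entries = entries,
                 mean_rsd = mean(entries$rsd[inc]),
                 mean_rsd_percent = 100 * mean(entries$rsd[inc]),
                 n_included = sum(inc), grand_mean_mode = grandMean),
            class = "RsdReport")
}

#' @export
print.RsdReport <- function(x, ...) {
  cat(sprintf("RsdReport: mean replicate RSD %.2f%% over %d included pairs (%d excluded)\n",
              x$mean_rsd_percent, x$n_included,
              sum(!is.na(x$entries$excluded))))
  invisible(x)
}

#' Per-feature QC dispersion
#'
#' Diagnostic report of QC repeatability: for each feature the RSD of the QC
#' intensities (sample sd over mean). Not used as an acceptance filter —
#' provided for inspection alongside the replicate-RSD assessment.
#'
#' @param x a [PeakSet-class] with at least two QC observations.
#' @return data.frame with `feature_id`, `qc_mean`, `qc_sd`, `qc_rsd`.
#' @export
qcRsd <- function(x) {
  stopifnot(is(x, "PeakSet"))
  idx <- which(isQC(x))
  if (length(idx) < 2)
    stop("QC dispersion needs at least two QC observations", call. = FALSE)
  m <- intensityMatrix(x)[idx, , drop = FALSE]
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  data.frame(feature_id = featureIds(x), qc_mean = mu, qc_sd = sdv,
             qc_rsd = ifelse(mu > 0, sdv / mu, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Principal-component scores of a peak matrix
#'
#' Observations are mean-centred and every feature scaled to unit variance
#' (so that high-intensity peaks do not dominate) before the rotation.
#' Zero-variance features are dropped first (reported via `message()`). The
#' sign of each component is fixed so that the largest-magnitude element of
#' its loading vector is positive.
#'
#' @param x a [PeakSet-class] (all its observations enter the PCA).
#' @param nComponents number of leading components to return.
#' @return list with `scores` (observations x `nComponents`),
#'   `explained_variance` (fraction per returned component),
#'   `all_explained_variance` (full spectrum) and `dropped_features`.
#' @export
pcaScores <- function(x, nComponents = 2) {
  stopifnot(is(x, "PeakSet"))
  m <- intensityMatrix(x)
  if (nrow(m) < 2)
    stop("PCA needs at least two observations", call. = FALSE)
  v <- apply(m, 2, stats::var)
  dropped <- featureIds(x)[v == 0]
  if (length(dropped))
    message(length(dropped), " zero-variance feature(s) dropped before scaling")
  m <- m[, v > 0, drop = FALSE]
  maxRank <- min(nrow(m) - 1L, ncol(m))
  if (nComponents > maxRank)
    stop("nComponents = ", nComponents, " exceeds the available rank ",
         maxRank, call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  pc$x[, flip] <- -pc$x[, flip]
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(nComponents), drop = FALSE],
       explained_variance = ev[seq_len(nComponents)],
       all_explained_variance = ev,
       dropped_features = dropped)
}

#' MANOVA F statistic for group separation
#'
#' Wilks' lambda on the score columns with Rao's F approximation (exact for
#' two groups or two response variables); with a single response column this
#' reduces to the classical one-way ANOVA F. The F statistic is the
#' between-group to within-group variance ratio; its upper tail under the F
#' distribution gives the p value.
#'
#' @param scores numeric matrix, observations x response columns (typically
#'   the first two principal-component scores).
#' @param labels group label per observation; observations with `NA` labels
#'   are dropped.
#' @return list with `f_stat`, `p_value`, `df` (numerator, denominator),
#'   `wilks` (`NA` for the univariate case), `groups`.
#' @export
manovaF <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  keep <- !is.na(labels)
  scores <- scores[keep, , drop = FALSE]
  labels <- labels[keep]
  tab <- table(labels)
  if (length(tab) < 2)
    stop("MANOVA needs at least two groups", call. = FALSE)
  if (any(tab < 2))
    stop("every group needs at least two observations; too small: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  f <- factor(labels)
  if (ncol(scores) == 1) {
    a <- stats::anova(stats::lm(scores[, 1] ~ f))
    return(list(f_stat = a$`F value`[1], p_value = a$`Pr(>F)`[1],
                df = c(a$Df[1], a$Df[2]), wilks = NA_real_,
                groups = levels(f)))
  }
  st <- tryCatch(
    summary(stats::manova(scores ~ f), test = "Wilks")$stats,
    error = function(e)
      stop("MANOVA failed (singular within-group covariance? try fewer ",
           "components): ", conditionMessage(e), call. = FALSE))
  list(f_stat = unname(st[1, "approx F"]), p_value = unname(st[1, "Pr(>F)"]),
       df = unname(c(st[1, "num Df"], st[1, "den Df"])),
       wilks = unname(st[1, "Wilks"]), groups = levels(f))
}

#' PCA-MANOVA group/batch separation score
#'
#' Composition of [pcaScores()] and [manovaF()]: the scores of the first
#' `nComponents` principal components are computed once over all
#' experimental observations (QCs carry no group and are always excluded),
#' and the MANOVA then tests the requested labels on those shared
#' coordinates — batch F and group F are therefore directly comparable, as
#' both ask how much of the dominant variance the labelling explains. With
#' an ideal correction the largest source of variation is the experimental
#' grouping rather than the acquisition batch, so the batch F should drop
#' below the group F.
#'
#' @param x a [PeakSet-class].
#' @param grouping `"group"` or `"batch"` — which label to test.
#' @param groups optional subset of group labels to compare (e.g.
#'   `c("C", "D")`); observations outside them are excluded from the MANOVA
#'   (not from the PCA). Ignored for `grouping = "batch"`.
#' @param nComponents number of principal components scored (2, classically).
#' @return a `PcaManovaReport` (S3 list): `scores` (all experimental
#'   observations), `explained_variance`, `f_stat`, `p_value`, `df`,
#'   `grouping`, `groups`.
#' @export
pcaManova <- function(x, grouping = c("group", "batch"), groups = NULL,
                      nComponents = 2) {
  stopifnot(is(x, "PeakSet"))
  grouping <- match.arg(grouping)
  keep <- obsRole(x) == "experimental"
  labels <- if (grouping == "group") obsGroup(x) else as.character(batchId(x))
  labels[!keep] <- NA_character_
  if (grouping == "group" && !is.null(groups))
    labels[!labels %in% groups] <- NA_character_
  if (length(unique(labels[!is.na(labels)])) < 2)
    stop("PCA-MANOVA needs at least two ", grouping, " labels among the ",
         "experimental observations", call. = FALSE)
  pc <- pcaScores(x[, keep], nComponents)
  mf <- manovaF(pc$scores, labels[keep])
  structure(list(scores = pc$scores,
                 explained_variance = pc$explained_variance,
                 f_stat = mf$f_stat, p_value = mf$p_value, df = mf$df,
                 grouping = grouping, groups = mf$groups),
            class = "PcaManovaReport")
}

#' @export
print.PcaManovaReport <- function(x, ...) {
  cat(sprintf("PCA-MANOVA (%s: %s): F = %.3f (df %g, %g), p = %.3g\n",
              x$grouping, paste(x$groups, collapse = "/"),
              x$f_stat, x$df[1], x$df[2], x$p_value))
  invisible(x)
}
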