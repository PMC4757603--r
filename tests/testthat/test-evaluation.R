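test_that("replicate RSD handles exact replicates and small sets", {
  lay <- makeLayout(1, 6, 6)
  lay$group <- ifelse(lay$role == "experimental", "C", NA)
  lay$replicate_set <- NA_character_
  lay$replicate_set[lay$role == "experimental"] <-
    c("s1", "s1", "s1", "s2", "s2", NA)
  m <- matrix(4, nrow(lay), 1)
  ps <- PeakSet(m, lay)
  rep <- replicateRsd(ps)
  e <- rep$entries
  expect_equal(e$rsd[e$replicate_set == "s1"], 0)
  expect_equal(e$excluded[e$replicate_set == "s2"], "set_too_small")
  expect_equal(rep$mean_rsd, 0)
})

test_that("replicate RSD matches a naive double-loop oracle", {
  ps <- randomPeakSet(nBatches = 2, nExp = 12, nFeat = 8, seed = 41)
  X <- intensityMatrix(ps)
  X[3, 2] <- 0                         # trips the zero-in-original rule
  intensityMatrix(ps) <- X
  rep <- replicateRsd(ps)
  rs <- replicateSet(ps); expi <- which(obsRole(ps) == "experimental")
  acc <- c(); n <- 0
  for (s in sort(unique(stats::na.omit(rs)))) {
    idx <- intersect(which(!is.na(rs) & rs == s), expi)
    if (length(idx) < 3) next
    for (p in seq_len(ncol(X))) {
      vals <- X[idx, p]
      if (any(vals == 0)) next
      gm <- mean(X[expi, p])
      if (gm == 0 || all(vals == 0)) next
      acc <- c(acc, stats::sd(vals) / gm); n <- n + 1
    }
  }
  expect_equal(rep$mean_rsd, mean(acc), tolerance = 1e-12)
  expect_equal(rep$n_included, n)
})

test_that("exclusion reasons are assigned one per entry", {
  lay <- makeLayout(1, 6, 6)
  lay$group <- ifelse(lay$role == "experimental", "C", NA)
  lay$replicate_set <- NA_character_
  lay$replicate_set[lay$role == "experimental"] <- rep(c("s1", "s2"), each = 3)
  m <- matrix(5, nrow(lay), 3)
  orig <- m
  orig[1, 1] <- 0                       # s1/f1: zero in original
  m[lay$replicate_set %in% "s2", 2] <- 0  # s2/f2: all zero corrected
  psO <- PeakSet(orig, lay)
  psC <- PeakSet(m, lay)
  rep <- replicateRsd(psC, original = psO)
  e <- rep$entries
  expect_equal(e$excluded[e$replicate_set == "s1" & e$feature_id == "F0001"],
               "zero_in_original")
  expect_equal(e$excluded[e$replicate_set == "s2" & e$feature_id == "F0002"],
               "all_zero_corrected")
  expect_true(all(is.na(e$excluded) |
                    e$excluded %in% c("set_too_small", "zero_in_original",
                                      "all_zero_corrected",
                                      "zero_grand_mean")))
})

test_that("mean RSD is invariant to feature order and per-feature scaling", {
  ps <- randomPeakSet(nBatches = 2, nExp = 12, nFeat = 6, seed = 42)
  base <- replicateRsd(ps)$mean_rsd
  perm <- ps[sample(6), ]
  expect_equal(replicateRsd(perm)$mean_rsd, base, tolerance = 1e-12)
  X <- intensityMatrix(ps); X[, 4] <- X[, 4] * 7.3
  ps2 <- ps; intensityMatrix(ps2) <- X
  expect_equal(replicateRsd(ps2)$mean_rsd, base, tolerance = 1e-12)
})

test_that("PCA scores reproduce an SVD oracle up to component sign", {
  ps <- randomPeakSet(nBatches = 2, nExp = 18, nFeat = 12, seed = 43)
  pc <- pcaScores(ps, nComponents = 3)
  m <- scale(intensityMatrix(ps))
  sv <- svd(m)
  oracle <- sv$u %*% diag(sv$d)
  for (j in 1:3) {
    s <- oracle[, j]
    expect_true(max(abs(pc$scores[, j] - s)) < 1e-8 ||
                  max(abs(pc$scores[, j] + s)) < 1e-8)
  }
  expect_equal(sum(pc$all_explained_variance), 1, tolerance = 1e-12)
  expect_true(all(diff(pc$all_explained_variance) <= 1e-12))
  expect_error(pcaScores(ps, nComponents = 50), "rank")
})

test_that("duplicated observations get identical scores; zero-variance features drop", {
  ps <- randomPeakSet(nBatches = 1, nExp = 6, nFeat = 6, seed = 44)
  X <- intensityMatrix(ps)
  X[2, ] <- X[1, ]
  X[, 5] <- 3                          # constant feature
  intensityMatrix(ps) <- X
  expect_message(pc <- pcaScores(ps, 2), "zero-variance")
  expect_equal(pc$scores[1, ], pc$scores[2, ], tolerance = 1e-10)
  expect_equal(pc$dropped_features, featureIds(ps)[5])
})

test_that("two-group two-PC MANOVA F equals the Hotelling T2 transform", {
  set.seed(45)
  n1 <- 14; n2 <- 17
  scores <- rbind(matrix(stats::rnorm(2 * n1), ncol = 2),
                  matrix(stats::rnorm(2 * n2, mean = 0.8), ncol = 2))
  labels <- rep(c("A", "B"), c(n1, n2))
  mf <- manovaF(scores, labels)
  # Hotelling T2 oracle
  m1 <- colMeans(scores[1:n1, ]); m2 <- colMeans(scores[-(1:n1), ])
  S <- ((n1 - 1) * stats::cov(scores[1:n1, ]) +
        (n2 - 1) * stats::cov(scores[-(1:n1), ])) / (n1 + n2 - 2)
  t2 <- (n1 * n2 / (n1 + n2)) *
    drop(t(m1 - m2) %*% solve(S) %*% (m1 - m2))
  fOracle <- t2 * (n1 + n2 - 3) / (2 * (n1 + n2 - 2))
  expect_equal(mf$f_stat, fOracle, tolerance = 1e-10)
  expect_equal(mf$df, c(2, n1 + n2 - 3))
  expect_equal(mf$p_value,
               stats::pf(fOracle, 2, n1 + n2 - 3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("single-response MANOVA reduces to one-way ANOVA", {
  set.seed(46)
  y <- stats::rnorm(30)
  g <- rep(c("A", "B", "C"), 10)
  mf <- manovaF(matrix(y, ncol = 1), g)
  a <- stats::anova(stats::lm(y ~ factor(g)))
  expect_equal(mf$f_stat, a$`F value`[1], tolerance = 1e-12)
  expect_equal(mf$p_value, a$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("permuted labels give approximately uniform p-values", {
  set.seed(47)
  scores <- matrix(stats::rnorm(2 * 40), ncol = 2)
  labels <- rep(c("A", "B"), each = 20)
  ps <- replicate(500, {
    manovaF(scores, sample(labels))$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.05)
})

test_that("pcaManova separates injected shifts and rejects degenerate input", {
  ps <- randomPeakSet(nBatches = 2, nExp = 24, nFeat = 20, seed = 48,
                      groups = c("C", "D"))
  X <- intensityMatrix(ps)
  shift <- obsGroup(ps) == "D" & obsRole(ps) == "experimental"
  X[shift, ] <- X[shift, ] * 3
  intensityMatrix(ps) <- X
  pm <- pcaManova(ps, "group", groups = c("C", "D"))
  expect_lt(pm$p_value, 0.01)
  expect_true(pm$f_stat >= 0)
  lay <- makeLayout(1, 6, 6)
  lay$group <- ifelse(lay$role == "experimental", "C", NA)
  one <- PeakSet(matrix(stats::rlnorm(nrow(lay) * 4), ncol = 4), lay)
  expect_error(pcaManova(one, "group"), "two")
})

test_that("two groups from one distribution rarely separate (null calibration)", {
  set.seed(49)
  hits <- 0
  for (i in 1:60) {
    n <- 30
    scores <- matrix(stats::rnorm(2 * n), ncol = 2)
    labels <- rep(c("A", "B"), each = n / 2)
    mf <- manovaF(scores, labels)
    if (mf$p_value < 0.05) hits <- hits + 1
  }
  expect_lte(hits, 9)   # ~5% expected; allow binomial slack
})

test_that("QC dispersion report computes per-feature QC RSD", {
  ps <- randomPeakSet(nBatches = 2, nExp = 12, nFeat = 4, seed = 50)
  d <- qcRsd(ps)
  idx <- which(isQC(ps))
  v <- intensityMatrix(ps)[idx, 2]
  expect_equal(d$qc_rsd[2], stats::sd(v) / mean(v), tolerance = 1e-12)
})
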