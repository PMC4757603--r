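# fixtures are built in code; nothing is read from disk except round-trip
# temp files created inside tests

# a minimal hand-laid two-batch peak set: each batch has `nExp` experimental
# injections with a QC after every `qcEvery`
makeLayout <- function(nBatches = 2, nExp = 12, qcEvery = 6) {
  rows <- do.call(rbind, lapply(seq_len(nBatches), function(b) {
    roles <- character(0); placed <- 0
    while (placed < nExp) {
      blk <- min(qcEvery, nExp - placed)
      roles <- c(roles, rep("experimental", blk),
                 if (blk == qcEvery) "QC")
      placed <- placed + blk
    }
    data.frame(batch = b, role = roles)
  }))
  rows$run_index <- seq_len(nrow(rows))
  rows$sample_id <- sprintf("S%03d", rows$run_index)
  rows
}

randomPeakSet <- function(nBatches = 2, nExp = 12, nFeat = 5, qcEvery = 6,
                          seed = 1, groups = c("C", "D")) {
  set.seed(seed)
  lay <- makeLayout(nBatches, nExp, qcEvery)
  n <- nrow(lay)
  isExp <- lay$role == "experimental"
  lay$group <- NA_character_
  lay$replicate_set <- NA_character_
  nSets <- sum(isExp) %/% 3
  idx <- which(isExp)[seq_len(nSets * 3)]
  lay$replicate_set[idx] <- rep(sprintf("set%02d", seq_len(nSets)), each = 3)
  lay$group[idx] <- rep(groups[((seq_len(nSets) - 1) %% length(groups)) + 1],
                        each = 3)
  lay$group[isExp & is.na(lay$group)] <- groups[1]
  m <- matrix(stats::rlnorm(n * nFeat, meanlog = 7, sdlog = 0.3), n, nFeat,
              dimnames = list(NULL, sprintf("F%02d", seq_len(nFeat))))
  PeakSet(m, lay)
}

expect_trend_equal <- function(fit, expected, tol = 1e-10) {
  expect_equal(fit$factors, as.numeric(expected), tolerance = tol)
}
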