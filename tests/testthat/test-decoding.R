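# Wrap plain matrices into ConnectivitySequence objects on a fixed grid.
mockSeqObjects <- function(mats, step = 0.35, window = 0.375, t0 = 0) {
  lapply(mats, function(m)
    new("ConnectivitySequence", vecs = m, step = step, window = window,
        band = "alpha1", times = (seq_len(ncol(m)) - 1) * step, t0 = t0,
        channels = character()))
}

test_that("the confidence classifier separates, calibrates and respects label symmetry", {
  set.seed(91)
  X <- rbind(matrix(rnorm(40, -2), 10), matrix(rnorm(40, 2), 10))
  y <- rep(c("left", "right"), each = 10)
  clf <- fitConfidenceClassifier(X, y)
  expect_equal(predictClass(clf, X), y)
  conf <- predictConfidence(clf, X)
  expect_true(all(conf >= -1 & conf <= 1))
  expect_true(all(sign(conf) == ifelse(y == "right", 1, -1)))
  # a pattern midway between the classes has low confidence
  expect_lt(abs(predictConfidence(clf, matrix(0, 1, 4))), 0.35)
  # flipping all labels flips all confidence signs
  clf2 <- fitConfidenceClassifier(X, rev(y))
  expect_equal(predictConfidence(clf2, X), -conf, tolerance = 1e-6)
  expect_error(fitConfidenceClassifier(X, rep("left", 20)), "both classes")
  expect_error(fitConfidenceClassifier(X[1:3, ], c("left", "left", "right")),
               "2 samples")
})

test_that("static LOOCV re-selects features per fold without touching the held-out trial", {
  set.seed(97)
  n <- 8
  left <- matrix(runif(n * 25, 0.2, 0.5), n)
  right <- matrix(runif(n * 25, 0.2, 0.5), n)
  right[, 4] <- right[, 4] + 0.5
  right[, 17] <- right[, 17] + 0.5
  res <- loocvStaticAccuracy(left, right, k = 2)
  expect_equal(res$nFolds, 2L * n)
  expect_equal(res$nTrain, 2L * n - 1L)
  expect_length(res$predictions, 2L * n)
  expect_gte(res$accuracy, 0.9)
  # leak audit: every fold's selection is reproducible from the training
  # trials alone
  X <- rbind(left, right)
  y <- rep(c("left", "right"), each = n)
  for (i in c(1, 5, 12)) {
    tr <- setdiff(seq_len(2 * n), i)
    sel <- selectStaticFeatures(X[tr[y[tr] == "left"], ],
                                X[tr[y[tr] == "right"], ], k = 2)
    expect_identical(res$foldFeatures[[i]], sel)
  }
  expect_error(loocvStaticAccuracy(left[1, , drop = FALSE],
                                   right[1, , drop = FALSE]), "at least 4")
})

test_that("label-shuffled static decoding stays at chance level", {
  set.seed(101)
  A <- matrix(runif(10 * 30), 10)
  B <- matrix(runif(10 * 30), 10)
  res <- loocvStaticAccuracy(A, B, k = 5)
  # binomial 95% band around 0.5 for 20 predictions: about [0.25, 0.75]
  expect_gte(res$accuracy, 0.2)
  expect_lte(res$accuracy, 0.8)
})

test_that("time-resolved SVMs localize a transient planted contrast", {
  ms <- mockSequences(n = 10, npairs = 8, ntau = 10, shiftPairs = 2,
                      shiftCols = 3:5, shift = 0.8, seed = 103)
  seqL <- mockSeqObjects(ms$A)
  seqR <- mockSeqObjects(ms$B)
  trs <- timeResolvedSvms(seqL, seqR, selected = 2L)
  expect_length(trs$accuracy, 10L)
  expect_true(all(trs$accuracy[3:5] >= 0.9))
  expect_lt(mean(trs$accuracy[c(1:2, 7:10)]), 0.75)
  expect_equal(trs$step, 0.35)
  expect_error(timeResolvedSvms(seqL, seqR, integer(0)), "empty feature")
})

test_that("ensemble construction honours peaks, collisions and duplicate hyperplanes", {
  set.seed(107)
  mkClf <- function(rot) {
    X <- rbind(matrix(rnorm(60, -2), 15, 4), matrix(rnorm(60, 2), 15, 4))
    X <- sweep(X, 2, rot, "*")
    fitConfidenceClassifier(X, rep(c("left", "right"), each = 15))
  }
  a <- mkClf(c(1, 1, 1, 1))
  b <- mkClf(c(1, -1, 1, -1))
  c3 <- mkClf(c(-1, 1, -1, 1))
  # peaks at taus 3 (.95), 5 (.9), 9 (.93); window 1.05 s at step 0.35
  # means lags closer than 3 taps collide -> 5 is dropped against 3
  bank <- list(a, a, a, a, b, a, a, a, c3, a)
  curve <- c(.5, .6, .95, .5, .9, .55, .6, .5, .93, .5)
  ens <- buildEnsemble(curve, bank, step = 0.35, window = 1.05)
  expect_equal(ens@lags, c(3L, 9L))
  expect_true(all(diff(ens@lags) > 0))
  # duplicate hyperplanes are dropped: identical classifier at both peaks
  bank2 <- rep(list(a), 10)
  ens2 <- buildEnsemble(curve, bank2, step = 0.35, window = 1.05)
  expect_equal(length(ens2@members), 1L)
  # lag restriction excludes late peaks
  ens3 <- buildEnsemble(curve, bank, step = 0.35, window = 1.05,
                        maxLagSeconds = 1.5)
  expect_lte(max(ens3@lags), 5L)
  expect_error(new("EnsembleModel", members = list(a, b), lags = c(5L, 3L),
                   features = 1:2, step = .35, window = .7,
                   accuracy = c(.9, .9)),
               "increasing")
})

test_that("the ensemble readout implements the lagged averaging contract", {
  set.seed(109)
  mkClf <- function() {
    X <- rbind(matrix(rnorm(45, -1.5), 15, 3), matrix(rnorm(45, 1.5), 15, 3))
    fitConfidenceClassifier(X, rep(c("left", "right"), each = 15),
                            features = 1:3)
  }
  ens <- new("EnsembleModel", members = list(mkClf(), mkClf()),
             lags = c(2L, 6L), features = 1:3, step = 0.35, window = 0.7,
             accuracy = c(.9, .9))
  m <- matrix(runif(5 * 12, 0, 1), 5)  # 5 pairs x 12 windows
  s <- mockSeqObjects(list(m))[[1]]
  ro <- ensembleReadout(s, ens)
  expect_equal(dim(ro$Z), c(2L, 12L))
  expect_true(all(abs(ro$Z) <= 1))
  expect_length(ro$z, 12L - 6L)
  # lagged combination contract: z(t) = mean over members of Z[i, t + lag_i]
  for (t0i in 0:5)
    expect_equal(ro$z[t0i + 1],
                 mean(c(ro$Z[1, t0i + 2], ro$Z[2, t0i + 6])))
  expect_true(all(ro$z >= -1 & ro$z <= 1))
  # stream shorter than the largest lag: empty trace with a warning
  short <- mockSeqObjects(list(m[, 1:5]))[[1]]
  expect_warning(ro2 <- ensembleReadout(short, ens), "shorter")
  expect_length(ro2$z, 0L)
  # step mismatch is an error
  bad <- mockSeqObjects(list(m), step = 0.02)[[1]]
  expect_error(ensembleReadout(bad, ens), "step")
})
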