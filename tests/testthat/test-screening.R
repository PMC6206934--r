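test_that("Wilcoxon score equals the standardized rank-sum on hand examples", {
  expect_equal(wilcoxonScores(matrix(1:3), matrix(4:6)),
               4.5 / sqrt(5.25), tolerance = 1e-6)
  # identical groups: every observation tied -> zero variance -> score 0
  expect_equal(wilcoxonScores(matrix(rep(2, 3)), matrix(rep(2, 3))), 0)
  # rank-based: invariant under monotone transforms
  set.seed(13)
  A <- matrix(runif(40), 8); B <- matrix(runif(40), 8)
  expect_equal(wilcoxonScores(A, B), wilcoxonScores(exp(3 * A), exp(3 * B)),
               tolerance = 1e-12)
  expect_error(wilcoxonScores(matrix(1:2, 1), matrix(1:2, 1)), "2 patterns")
})

test_that("Wilcoxon score matches the exhaustive permutation-distribution oracle", {
  set.seed(17)
  for (rep in 1:8) {
    nA <- sample(3:4, 1); nB <- sample(3:4, 1)
    a <- round(runif(nA), 2)  # rounding induces occasional ties
    b <- round(runif(nB), 2)
    got <- wilcoxonScores(matrix(rep(a, 2), nA), matrix(rep(b, 2), nB))
    expect_equal(got[1], rankSumZExact(a, b), tolerance = 1e-10)
    expect_equal(got[2], got[1])
  }
})

test_that("static selection returns the k best couplings, stable under ties", {
  set.seed(19)
  A <- matrix(runif(12 * 30), 12); B <- matrix(runif(12 * 30), 12)
  B[, 7] <- B[, 7] + 2                 # one perfectly separating feature
  expect_equal(selectStaticFeatures(A, B, k = 1), 7L)
  sel <- selectStaticFeatures(A, B, k = 10)
  expect_length(sel, 10L)
  expect_true(7L %in% sel)
  expect_error(selectStaticFeatures(A, B, k = 31), "exceeds")
  # tie stability: constant data scores all-zero, selection is the first k
  Z <- matrix(1, 6, 5)
  expect_equal(selectStaticFeatures(Z, Z, k = 3), 1:3)
})

test_that("latency-resolved scores localize a planted window and are flat under the null", {
  ms <- mockSequences(shiftPairs = 3, shiftCols = 10:16, shift = 0.8)
  sc <- timeIndexedScores(ms$A, ms$B)
  expect_equal(dim(sc), c(20L, 30L))
  expect_true(all(sc[3, 10:16] > 3))
  expect_lt(max(sc[3, c(1:7, 20:30)]), 3)
  # relabeled data: no systematic structure
  null <- mockSequences(seed = 23)
  scn <- timeIndexedScores(null$A, null$B)
  expect_lt(mean(scn), 1.2)  # E|z| under H0 is about 0.8
  short <- null$A
  short[[1]] <- short[[1]][, 1:10]
  expect_error(timeIndexedScores(short, null$B), "disagree")
})

test_that("the permutation threshold is seeded, monotone, and calibrated at 99.9%", {
  null <- mockSequences(npairs = 30, ntau = 40, seed = 29)
  thr1 <- permutationThreshold(null$A, null$B, nRand = 50, seed = 5)
  thr2 <- permutationThreshold(null$A, null$B, nRand = 50, seed = 5)
  expect_equal(as.numeric(thr1), as.numeric(thr2))
  thr95 <- permutationThreshold(null$A, null$B, nRand = 50, seed = 5,
                                percentile = 0.95)
  expect_gt(as.numeric(thr1), as.numeric(thr95))
  expect_error(permutationThreshold(null$A, null$B, nRand = 5), "at least 20")
})

test_that("the consistency sieve removes short supra-threshold runs", {
  # isolated single-latency exceedance is eliminated by a 5-tap median
  sc <- matrix(0, 2, 9)
  sc[1, 5] <- 10
  res <- consistencyProfile(sc, threshold = 1, medianWindow = 5)
  expect_equal(pairProfile(res)[1], 0)
  expect_length(selectedPairs(res), 0)
  # run as long as the window survives
  sc[2, 3:7] <- 10
  res <- consistencyProfile(sc, threshold = 1, medianWindow = 5)
  expect_equal(pairProfile(res)[2], 5)
  expect_equal(selectedPairs(res), 2L)
  # an always-supra row keeps its full latency count
  sc2 <- matrix(10, 1, 12)
  res2 <- consistencyProfile(sc2, threshold = 1, medianWindow = 5)
  expect_equal(pairProfile(res2), 12)
  # default window honours the 100 ms persistence floor
  expect_equal(plvbci:::oddMedianWindow(0.02), 11L)
  expect_equal(plvbci:::oddMedianWindow(0.35), 3L)
})

test_that("bootstrap aggregation recovers a persistent planted coupling", {
  ms <- mockSequences(shiftPairs = c(4, 9), shiftCols = 8:22, shift = 0.8,
                      seed = 31)
  res <- bootstrapSelect(ms$A, ms$B, nBoot = 10, nRand = 30, step = 0.02,
                         seed = 3)
  expect_true(all(c(4L, 9L) %in% selectedPairs(res)))
  expect_lte(length(selectedPairs(res)), 6L)
  expect_equal(res@nBoot, 10L)
  # determinism: selection is a function of (data, seed)
  res2 <- bootstrapSelect(ms$A, ms$B, nBoot = 10, nRand = 30, step = 0.02,
                          seed = 3)
  expect_identical(selectedPairs(res), selectedPairs(res2))
})

test_that("pure-noise data triggers the static fallback with a warning", {
  null <- mockSequences(npairs = 10, ntau = 25, seed = 37)
  expect_warning(
    res <- bootstrapSelect(null$A, null$B, nBoot = 5, nRand = 25,
                           step = 0.02, seed = 1, fallbackK = 4),
    "fall")
  expect_length(selectedPairs(res), 4L)
})
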