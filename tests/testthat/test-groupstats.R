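test_that("common good-sensor intersection is order-stable and guards emptiness", {
  expect_equal(commonGoodSensors(list(c("A", "B", "C"), c("B", "C", "D"))),
               c("B", "C"))
  expect_equal(commonGoodSensors(list(c("C3", "Cz", "C4"))),
               c("C3", "Cz", "C4"))
  expect_error(commonGoodSensors(list(c("A", "B"), c("C", "D"))),
               "no sensor")
})

test_that("coupling contrast flags a planted shift with the right sign and FDR control", {
  set.seed(61)
  nsub <- 6; npairs <- 40
  A <- matrix(runif(nsub * npairs, 0.2, 0.5), nsub)
  B <- matrix(runif(nsub * npairs, 0.2, 0.5), nsub)
  # a 6v6 exact rank-sum test bottoms out at p = 2/choose(12,6) ~ 0.0022,
  # so several shifted couplings are needed for BH at alpha = 0.05 over 40
  # features to reject
  shifted <- c(5, 13, 22)
  A[, shifted] <- A[, shifted] + 0.4
  gc <- compareCouplings(A, B)
  expect_true(all(gc$significant[shifted]))
  expect_true(all(gc$medianDiff[shifted] > 0))
  expect_false(any(gc$significant[-shifted]))
  # corrected mask is never more liberal than the uncorrected one
  expect_true(all(which(gc$significant) %in% which(gc$p < 0.05)))
  # identical groups: nothing survives
  gc0 <- compareCouplings(A, A)
  expect_false(any(gc0$significant))
  expect_error(compareCouplings(A[1, , drop = FALSE], B), "2 subjects")
})

test_that("Benjamini-Hochberg agrees with the brute-force ordered-p rule", {
  set.seed(67)
  for (rep in 1:5) {
    p <- c(runif(12), runif(8, 0, 0.01))[sample(20)]
    alpha <- 0.05
    # brute force: largest k with p_(k) <= k/m * alpha, reject the k smallest
    o <- order(p)
    ps <- p[o]
    m <- length(p)
    k <- max(c(0, which(ps <= seq_len(m) / m * alpha)))
    rejBrute <- logical(m)
    if (k > 0) rejBrute[o[seq_len(k)]] <- TRUE
    expect_equal(p.adjust(p, "BH") <= alpha, rejBrute)
  }
})

test_that("network-metric contrast flags only the shifted metric, Bonferroni-corrected", {
  set.seed(71)
  mkTriads <- function(geShift = 0) {
    grid <- expand.grid(subject = paste0("S", 1:6),
                        band = c("alpha1", "beta1"),
                        condition = c("rest", "left"),
                        metric = c("strength", "GE", "LE"),
                        stringsAsFactors = FALSE)
    grid$value <- runif(nrow(grid), 1, 2) +
      ifelse(grid$metric == "GE", geShift, 0)
    grid
  }
  A <- mkTriads(geShift = 3)
  B <- mkTriads()
  # 6v6 exact p bottoms out at ~0.0022; with a 12-cell Bonferroni family
  # the corrected floor is ~0.026, so test at alpha = 0.05
  out <- compareNetworkMetrics(A, B, alpha = 0.05)
  expect_true(all(out$significant[out$metric == "GE"]))
  expect_false(any(out$significant[out$metric == "strength"]))
  # subject order is irrelevant
  out2 <- compareNetworkMetrics(A[sample(nrow(A)), ], B, alpha = 0.05)
  expect_equal(out$significant, out2$significant)
  # identical cohorts: nothing flagged
  expect_false(any(compareNetworkMetrics(A, A, alpha = 0.05)$significant))
  bad <- A[A$band != "beta1", ]
  expect_error(compareNetworkMetrics(bad, B), "different")
})

test_that("family-wise error of the Bonferroni contrast stays near the nominal level", {
  set.seed(73)
  hits <- replicate(150, {
    grid <- expand.grid(subject = paste0("S", 1:6),
                        band = c("a", "b"), condition = "rest",
                        metric = c("strength", "GE", "LE"),
                        stringsAsFactors = FALSE)
    A <- grid; A$value <- rnorm(nrow(grid))
    B <- grid; B$value <- rnorm(nrow(grid))
    any(compareNetworkMetrics(A, B, alpha = 0.05)$significant)
  })
  expect_lt(mean(hits), 0.12)  # nominal 5% family-wise, generous band
})

test_that("the generic rank-sum utility supports one-tailed cohort comparisons", {
  set.seed(79)
  a <- rnorm(6, 1.5); b <- rnorm(6, 0)
  expect_lt(rankSumCompare(a, b, alternative = "greater"), 0.05)
  expect_gt(rankSumCompare(b, a, alternative = "greater"), 0.5)
})
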