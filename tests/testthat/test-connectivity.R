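fs <- 256

test_that("instantaneous phase tracks frequency, quadrature and amplitude invariance", {
  tt <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x <- rbind(cos(2 * pi * 10 * tt), sin(2 * pi * 10 * tt),
             5 * cos(2 * pi * 10 * tt))
  ph <- instantaneousPhase(x)
  mid <- 129:384
  # phase advances at 2*pi*f rad/s
  slope <- mean(diff(ph[1, mid]) %% (2 * pi)) * fs
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01)
  # sin lags cos by pi/2
  d <- (ph[1, mid] - ph[2, mid]) %% (2 * pi)
  expect_equal(mean(d), pi / 2, tolerance = 0.01)
  # amplitude does not affect phase
  expect_lt(max(abs(ph[1, ] - ph[3, ])), 1e-9)
  expect_warning(instantaneousPhase(matrix(0, 1, 100)), "undefined phase")
})

test_that("constant phase difference gives PLV 1 and the matrix contract holds", {
  tt <- seq(0, 3 - 1 / fs, by = 1 / fs)
  x <- rbind(cos(2 * pi * 9 * tt), cos(2 * pi * 9 * tt + 1.1))
  W <- plvAdjacency(plvMatrix(x, fs = fs))
  expect_equal(W[1, 2], 1, tolerance = 1e-6)
  expect_equal(diag(W), c(1, 1))
  expect_equal(W, t(W))
})

test_that("PLV of uniformly random phase differences matches the Rayleigh expectation", {
  set.seed(101)
  n <- 10000
  reps <- 300
  vals <- replicate(reps, {
    ph <- rbind(runif(n, -pi, pi), runif(n, -pi, pi))
    plvAdjacency(plvMatrix(ph, isPhase = TRUE))[1, 2]
  })
  expect_equal(mean(vals), sqrt(pi) / (2 * sqrt(n)), tolerance = 0.05)
  # second-moment calibration: E[PLV^2] = 1/n for independent phases
  expect_equal(mean(vals^2), 1 / n, tolerance = 0.1)
})

test_that("61 good sensors produce a 1830-length coupling vector in fixed order", {
  set.seed(7)
  x <- matrix(rnorm(61 * 256), 61)
  p <- plvMatrix(x, fs = fs)
  v <- vecW(p)
  expect_length(v, 1830L)
  map <- pairIndexMap(61)
  # vec ordering: row-major upper triangle, pair (i, j) at its mapped slot
  W <- plvAdjacency(p)
  idx <- sample.int(1830, 50)
  expect_equal(v[idx], W[cbind(map$i[idx], map$j[idx])])
})

test_that("vectorized PLV equals the naive per-pair loop to 1e-12", {
  set.seed(19)
  for (rep in 1:3) {
    x <- matrix(rnorm(8 * 512), 8)
    W <- plvAdjacency(plvMatrix(x, t1 = 0.25, t2 = 1.75, fs = fs))
    Wref <- plvLoop(x, from = round(0.25 * fs) + 1, to = round(1.75 * fs))
    expect_lt(max(abs(W - Wref)), 1e-12)
  }
})

test_that("PLV is invariant to a common phase offset", {
  set.seed(23)
  ph <- matrix(runif(3 * 1000, -pi, pi), 3)
  W1 <- plvAdjacency(plvMatrix(ph, isPhase = TRUE))
  W2 <- plvAdjacency(plvMatrix(ph + 0.83, isPhase = TRUE))
  expect_equal(W1, W2, tolerance = 1e-10)
})

test_that("sliding windows follow the cycle criterion and the window-count formula", {
  tt <- seq(0, 5 - 1 / fs, by = 1 / fs)
  x <- rbind(cos(2 * pi * 9 * tt), cos(2 * pi * 9 * tt + 0.7))
  s <- slidingConnectivity(x, "alpha1", step = 0.35, fs = fs)
  expect_equal(s@window, 3 / 8)        # 3 cycles of the 8 Hz low edge
  expect_equal(ncol(vecW(s)), 14L)     # floor((5 - 0.375)/0.35) + 1
  # a stationary constant-lag pair locks in every window
  expect_true(all(vecW(s)[1, ] > 1 - 1e-6))

  # property: window count formula across random trial lengths and steps
  set.seed(31)
  for (rep in 1:5) {
    L <- runif(1, 2, 6)
    step <- runif(1, 0.1, 0.5)
    y <- matrix(rnorm(2 * round(L * fs)), 2)
    sq <- slidingConnectivity(y, "alpha2", step = step, fs = fs)
    wlen <- round(3 / 10 * fs)
    slen <- round(step * fs)
    expect_equal(ncol(vecW(sq)),
                 length(seq.int(1L, ncol(y) - wlen + 1L, by = slen)))
  }
  expect_error(slidingConnectivity(x[, 1:64], "delta", fs = fs), "exceeds")
  expect_error(slidingConnectivity(x, "alpha1", step = 0, fs = fs))
})

test_that("trial sequences and static patterns share the vec ordering", {
  sets <- separableThetaSets()
  seqs <- trialSequences(sets$left, step = 0.35)
  expect_length(seqs, 20L)
  v <- vecW(seqs[[1]])
  expect_equal(nrow(v), 190L)  # 20 channels
  X <- staticPatterns(sets$left)
  expect_equal(dim(X), c(20L, 190L))
  expect_true(all(X >= 0 & X <= 1))
})
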