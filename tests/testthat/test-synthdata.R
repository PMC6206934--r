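test_that("schedules and configurations validate their invariants", {
  expect_error(couplingSchedule(pairs = rbind(c("C3", "C4")), band = "alpha1",
                                class = "left", from = 0, to = 1,
                                kappa = 1.2),
               "kappa")
  expect_error(couplingSchedule(pairs = rbind(c("C3", "C4")), band = "alpha1",
                                class = "left", from = 2, to = 1, kappa = 1),
               "from < to")
  expect_error(couplingSchedule(pairs = rbind(c("C3", "C4")), band = "alpha1",
                                class = "up", from = 0, to = 1, kappa = 1),
               "left")
  sched <- couplingSchedule(pairs = rbind(c("C3", "C4")), band = "alpha1",
                            class = "left", from = 0, to = 1, kappa = 0.5)
  # pairs must reference montage channels of the configured count
  expect_error(simulationConfig(nChannels = 8, schedule = sched),
               "unknown channels")
  # sampling must clear twice the highest band edge
  expect_error(simulationConfig(fs = 80), "Nyquist|twice")
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- simulationConfig(nChannels = 4, nTrialsPerClass = 2,
                          restLength = 16, restTrials = 2, seed = 9)
  r1 <- simulateRecording(cfg, "mi")
  r2 <- simulateRecording(cfg, "mi")
  expect_identical(r1@signal, r2@signal)
  expect_identical(eventTable(r1), eventTable(r2))
  r3 <- simulateRecording(simulationConfig(nChannels = 4,
                                           nTrialsPerClass = 2,
                                           restLength = 16, restTrials = 2,
                                           seed = 10), "mi")
  expect_false(identical(r1@signal, r3@signal))
})

test_that("the study dataset reproduces the experimental design counts", {
  study <- separableStudy()
  expect_equal(trialCount(study$left), 20L)
  expect_equal(trialCount(study$right), 20L)
  expect_equal(trialCount(study$rest_trials), 20L)
  expect_equal(nrow(eventTable(study$mi)), 40L)
  # 160 s of rest at 8 s per trial -> exactly 20 non-overlapping trials
  expect_equal(dim(study$rest_trials@data)[2], 8L * 256L)
  # trial counts follow the configuration
  small <- makeStudyDataset(simulationConfig(nChannels = 4,
                                             nTrialsPerClass = 5,
                                             restLength = 160, seed = 3))
  expect_equal(trialCount(small$left), 5L)
  expect_equal(trialCount(small$right), 5L)
  expect_equal(trialCount(small$rest_trials), 20L)
  expect_error(makeStudyDataset(simulationConfig(nChannels = 4,
                                                 restLength = 100,
                                                 seed = 3)),
               "too short")
})

test_that("a fully coupled pair locks and an uncoupled pair stays at the null level", {
  labs <- montageLabels(6)
  sched <- couplingSchedule(pairs = rbind(labs[c(1, 3)]), band = "alpha1",
                            class = "left", from = 0.5, to = 4.5,
                            kappa = 1, jitterSd = 0)
  cfg <- simulationConfig(nChannels = 6, nTrialsPerClass = 3,
                          restLength = 16, restTrials = 2, snrDb = 30,
                          schedule = sched, seed = 21)
  rec <- simulateRecording(cfg, "mi")
  filt <- bandpassFilter(rec, "alpha1")
  ev <- eventTable(rec)
  fs <- samplingRate(rec)
  planted <- c(); others <- c()
  for (i in which(ev$label == "left")) {
    from <- round(ev$onset[i] * fs) + 1L
    W <- plvAdjacency(plvMatrix(filt@signal[, from:(from + 5 * fs - 1)],
                                t1 = 0.7, t2 = 4.3, fs = fs))
    planted <- c(planted, W[1, 3])
    others <- c(others, W[1, 5], W[2, 6], W[4, 5])
  }
  expect_gt(min(planted), 0.9)
  # Monte-Carlo null for band-limited independent channels, same window
  set.seed(77)
  null <- replicate(200, {
    n <- round(3.6 * fs)
    a <- plvbci:::bandNoise(n, fs, 8, 10)
    b <- plvbci:::bandNoise(n, fs, 8, 10)
    Mod(mean(exp(1i * (Arg(a) - Arg(b)))))
  })
  expect_lt(mean(others), quantile(null, 0.99))
})

test_that("band-limited components concentrate their power inside the band", {
  cfg <- simulationConfig(nChannels = 2, nTrialsPerClass = 2,
                          restLength = 16, restTrials = 2, snrDb = 20,
                          seed = 33)
  rec <- simulateRecording(cfg, "rest")
  x <- bandpassFilter(rec, "alpha2")@signal[1, ]
  sp <- Mod(fft(x))^2
  freqs <- (seq_along(sp) - 1) * samplingRate(rec) / length(sp)
  half <- freqs <= samplingRate(rec) / 2
  peak <- freqs[half][which.max(sp[half])]
  expect_gte(peak, 10)
  expect_lte(peak, 13)
})

test_that("study trial sets are band-tagged, re-referenced and epoch-aligned", {
  sets <- separableThetaSets()
  expect_equal(sets$left@band, "theta")
  expect_equal(sets$left@t0, 0)
  tr <- getTrial(sets$left, 1)
  expect_lt(max(abs(colMeans(tr))), 1e-9)
  stream <- studyTrialSets(separableStudy(), band = "theta",
                           window = c(-3, 5))
  expect_equal(stream$left@t0, -3)
  expect_equal(dim(stream$left@data)[2], 8L * 256L)
})
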