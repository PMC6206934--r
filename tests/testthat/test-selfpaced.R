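# Fabricated ensemble readouts on the streaming grid: 8 s epochs, 20 ms
# step, epoch starting 3 s before the (possible) cue.
mockReadout <- function(kind = c("mi", "rest"), sign = 1, seed = 1,
                        len = 330, step = 0.02) {
  kind <- match.arg(kind)
  set.seed(seed)
  onsetTimes <- (seq_len(len) - 1) * step - 3
  z <- rnorm(len, 0, 0.08)
  if (kind == "mi") {
    bump <- onsetTimes >= 0 & onsetTimes <= 2
    z[bump] <- z[bump] + sign * 0.85
  }
  structure(list(Z = NULL, z = pmax(-1, pmin(1, z)),
                 onsetTimes = onsetTimes, step = step, t0 = -3),
            class = "ensembleReadout")
}

mockSwitchData <- function(nMi = 20, nRest = 10) {
  mi <- lapply(seq_len(nMi), function(i)
    mockReadout("mi", sign = ifelse(i %% 2, -1, 1), seed = i))
  rest <- lapply(seq_len(nRest), function(i)
    mockReadout("rest", seed = 100 + i))
  list(mi = mi, rest = rest)
}

test_that("the switch trains on 100 MI-event and 100 baseline-state segments", {
  d <- mockSwitchData()
  sw <- trainSwitch(d$mi, d$rest)
  expect_s4_class(sw, "SwitchModel")
  expect_equal(unname(sw@segmentCounts["mi"]), 100L)       # 20 trials x 5
  expect_equal(unname(sw@segmentCounts["baseline"]), 100L) # equal count
  expect_equal(sw@width, 0.5)
  expect_equal(sw@threshold, 0.5)
  expect_error(trainSwitch(d$mi, d$rest, interval = c(0.2, 0.5)),
               "shorter than the segment width")
})

test_that("stream decoding flags sustained events with the right direction and persistence", {
  d <- mockSwitchData()
  sw <- trainSwitch(d$mi, d$rest)
  # held-out MI trace: one detection near the onset, matching direction
  detL <- streamDecode(mockReadout("mi", sign = -1, seed = 501), sw)
  expect_equal(nrow(detL), 1L)
  expect_equal(detL$direction, -1)
  expect_gte(detL$time, -0.6)
  expect_lte(detL$time, 1.5)
  detR <- streamDecode(mockReadout("mi", sign = 1, seed = 502), sw)
  expect_equal(detR$direction, 1)
  # rest-only trace: no detections
  expect_equal(nrow(streamDecode(mockReadout("rest", seed = 503), sw)), 0L)
  # an unreachable confidence threshold silences the detector
  expect_equal(nrow(streamDecode(mockReadout("mi", seed = 504), sw,
                                 threshold = 1)), 0L)
  # flickers shorter than the persistence floor are discarded
  flick <- mockReadout("rest", seed = 505)
  mid <- which(flick$onsetTimes >= 0 & flick$onsetTimes < 0.2)
  flick$z[mid] <- 0.85
  expect_equal(nrow(streamDecode(flick, sw)), 0L)
})

test_that("self-paced error scoring counts per-trial misses and false alarms", {
  d <- mockSwitchData()
  sw <- trainSwitch(d$mi[1:10], d$rest[1:5])
  set.seed(9)
  clfX <- rbind(matrix(rnorm(30, -2), 15), matrix(rnorm(30, 2), 15))
  clf <- fitConfidenceClassifier(clfX, rep(c("left", "right"), each = 15))
  ens <- new("EnsembleModel", members = list(clf), lags = 1L,
             features = 1:2, step = 0.02, window = 0.75, accuracy = 0.9)
  model <- list(ensemble = ens, switch = sw)
  # bypass ensembleReadout by evaluating streamDecode directly on traces
  score <- function(readouts, isMi) {
    fp <- 0L; fn <- 0L
    for (r in readouts) {
      det <- streamDecode(r, sw)
      hit <- nrow(det) > 0 && any(det$time >= -0.5 & det$time <= 2.5)
      false <- nrow(det) > 0 && any(det$time < -0.5 | det$time > 2.5)
      if (isMi && !hit) fn <- fn + 1L
      if (false || (!isMi && nrow(det) > 0)) fp <- fp + 1L
    }
    c(fp, fn)
  }
  mi <- score(lapply(601:610, function(s) mockReadout("mi", seed = s)), TRUE)
  rest <- score(lapply(701:705, function(s) mockReadout("rest", seed = s)),
                FALSE)
  expect_equal(mi[2], 0L)    # every event detected
  expect_equal(rest[1], 0L)  # no baseline false alarm
})
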