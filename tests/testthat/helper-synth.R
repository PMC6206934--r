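# Shared synthetic fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# The canonical separable synthetic subject: five theta-band couplings per
# imagery class on distinct sensor pairs, active through most of the imagery
# interval, on a 20-channel montage.
separablePairs <- function(nChannels = 20) {
  labs <- montageLabels(nChannels)
  list(left = rbind(labs[c(1, 3)], labs[c(5, 7)], labs[c(9, 11)],
                    labs[c(13, 15)], labs[c(17, 19)]),
       right = rbind(labs[c(2, 4)], labs[c(6, 8)], labs[c(10, 12)],
                     labs[c(14, 16)], labs[c(18, 20)]))
}

separableSchedule <- function(nChannels = 20, band = "theta",
                              from = 0.3, to = 4.5, kappa = 0.8,
                              jitterSd = 0.02) {
  p <- separablePairs(nChannels)
  couplingSchedule(
    pairs = rbind(p$left, p$right),
    band = band, class = rep(c("left", "right"), each = 5),
    from = from, to = to, kappa = kappa, jitterSd = jitterSd)
}

separableConfig <- function(seed = 42, nChannels = 20, ...) {
  simulationConfig(nChannels = nChannels, nTrialsPerClass = 20,
                   restLength = 160,
                   schedule = separableSchedule(nChannels, ...), seed = seed)
}

# vec(W) positions of the planted couplings, by class
separablePlanted <- function(nChannels = 20) {
  p <- separablePairs(nChannels)
  map <- pairIndexMap(nChannels)
  labs <- montageLabels(nChannels)
  pos <- function(m) apply(m, 1, function(pr) {
    i <- match(pr[1], labs); j <- match(pr[2], labs)
    map$pair[map$i == min(i, j) & map$j == max(i, j)]
  })
  list(left = pos(p$left), right = pos(p$right))
}

separableStudy <- function() {
  fixture("separableStudy", function() makeStudyDataset(separableConfig()))
}

separableThetaSets <- function() {
  fixture("separableThetaSets",
          function() studyTrialSets(separableStudy(), band = "theta"))
}

# Same subject but with the couplings confined to a transient window
# (0.5-2.5 s after the cue), for latency-localization checks.
transientStudy <- function() {
  fixture("transientStudy", function()
    makeStudyDataset(separableConfig(from = 0.5, to = 2.5)))
}

# Streaming (20 ms) connectivity data of the separable subject.
separableStream <- function() {
  fixture("separableStream",
          function() selfPacedData(separableStudy(), band = "theta",
                                   step = 0.02))
}

# Small synthetic sequence sets built directly at the pattern level: two
# groups of N_pairs x N_tau matrices with a shift planted in chosen cells.
mockSequences <- function(n = 12, npairs = 20, ntau = 30, shiftPairs = NULL,
                          shiftCols = NULL, shift = 1, seed = 1) {
  set.seed(seed)
  mk <- function(withShift) replicate(n, {
    m <- matrix(runif(npairs * ntau, 0.2, 0.6), npairs)
    if (withShift && length(shiftPairs))
      m[shiftPairs, shiftCols] <- m[shiftPairs, shiftCols] + shift
    m
  }, simplify = FALSE)
  list(A = mk(TRUE), B = mk(FALSE))
}

# A deliberately small pipeline subject for fast end-to-end runs: 8
# channels, 8 trials per class, one Monte-Carlo split, reduced resampling.
tinyPipelineConfig <- function(seed = 11) {
  labs <- montageLabels(8)
  sched <- couplingSchedule(
    pairs = rbind(labs[c(1, 3)], labs[c(5, 7)],
                  labs[c(2, 4)], labs[c(6, 8)]),
    band = "theta", class = rep(c("left", "right"), each = 2),
    from = 0.3, to = 4.5, kappa = 0.8, jitterSd = 0.02)
  sim <- simulationConfig(nChannels = 8, nTrialsPerClass = 8,
                          restLength = 80, restTrials = 10,
                          schedule = sched, seed = seed)
  pipelineConfig(sim = sim, band = "theta", stepStreaming = 0.06,
                 nRand = 25, nBoot = 5, nSplits = 1, seed = seed)
}

# A small label-free recording for preprocessing/io tests.
tinyRecording <- function(nch = 4, seconds = 4, fs = 128, seed = 11) {
  set.seed(seed)
  sig <- matrix(rnorm(nch * seconds * fs), nch)
  new("EEGRecording", signal = sig, fs = fs,
      channels = montageLabels(nch),
      events = data.frame(onset = c(1, 2.5),
                          label = c("left", "right"),
                          stringsAsFactors = FALSE))
}
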