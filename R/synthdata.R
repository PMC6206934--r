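#' @include preprocess.R connectivity.R
NULL

#' Coupling schedule for the synthetic-EEG generator
#'
#' Describes which channel pairs become phase-coupled, in which rhythm, for
#' which imagery class, and when (relative to the cue onset). During a
#' scheduled window both channels' band component is drawn towards a shared
#' latent oscillation: the analytic components mix as
#' A = (1 - kappa) A_own + kappa A_latent exp(i jitter), so kappa = 1 with
#' zero jitter yields perfect phase locking and kappa = 0 leaves the
#' channels independent.
#'
#' @param pairs two-column matrix or data.frame of channel labels (or a
#'   list of length-2 vectors), one row per planted coupling.
#' @param band band name per entry (recycled).
#' @param class \code{"left"} or \code{"right"} per entry (recycled).
#' @param from,to latency window in seconds relative to cue onset (recycled).
#' @param kappa coupling strength in [0, 1] (recycled).
#' @param jitterSd SD (radians) of the Gaussian phase jitter each coupled
#'   channel adds to the latent phase.
#' @param noiseExponent spectral exponent of the 1/f^a background noise.
#' @return object of class \code{couplingSchedule} (a validated list).
#' @examples
#' couplingSchedule(pairs = rbind(c("C3", "C4")), band = "alpha1",
#'                  class = "left", from = 0.5, to = 2.5, kappa = 0.8)
#' @export
couplingSchedule <- function(pairs = NULL, band = character(),
                             class = character(), from = numeric(),
                             to = numeric(), kappa = numeric(),
                             jitterSd = 0.1, noiseExponent = 1) {
  if (is.null(pairs)) {
    entries <- data.frame(chA = character(), chB = character(),
                          band = character(), class = character(),
                          from = numeric(), to = numeric(), kappa = numeric(),
                          stringsAsFactors = FALSE)
  } else {
    if (is.list(pairs) && !is.data.frame(pairs))
      pairs <- do.call(rbind, pairs)
    pairs <- as.matrix(pairs)
    n <- nrow(pairs)
    entries <- data.frame(chA = as.character(pairs[, 1]),
                          chB = as.character(pairs[, 2]),
                          band = rep_len(band, n),
                          class = rep_len(class, n),
                          from = rep_len(from, n), to = rep_len(to, n),
                          kappa = rep_len(kappa, n),
                          stringsAsFactors = FALSE)
  }
  if (any(entries$kappa < 0 | entries$kappa > 1))
    stop("coupling strength kappa must lie in [0, 1]")
  if (any(entries$from >= entries$to))
    stop("coupling windows need from < to")
  bad <- setdiff(unique(entries$class), c("left", "right"))
  if (length(bad))
    stop("schedule classes must be 'left' or 'right', got: ",
         paste(bad, collapse = ", "))
  structure(list(entries = entries, jitterSd = jitterSd,
                 noiseExponent = noiseExponent),
            class = "couplingSchedule")
}

#' Simulation configuration emulating the study design
#'
#' Defaults reproduce the recording design the pipeline targets: 61 channels
#' (10-10 montage) at 256 Hz, 20 cued motor-imagery trials per class with a
#' 3 s fixation followed by 5 s of imagery, and a 3-minute rest recording
#' that is cut into 20 non-overlapping 8 s baseline trials.
#'
#' @param nChannels number of channels (10-10 labels for up to 61).
#' @param fs sampling rate in Hz; must exceed twice the highest band edge.
#' @param nTrialsPerClass cued trials per imagery class.
#' @param trialLength imagery duration per trial in seconds.
#' @param fixation fixation-cross duration before each cue, seconds.
#' @param restLength length of the rest recording in seconds.
#' @param restTrials,restTrialLength how the rest recording is cut into
#'   baseline trials.
#' @param schedule a [couplingSchedule()].
#' @param snrDb total oscillation-to-background power ratio per channel, dB.
#' @param seed master seed; every random draw derives from it through
#'   per-trial sub-streams.
#' @param bands band table (drives oscillation centre frequencies).
#' @return object of class \code{simulationConfig} (a validated list).
#' @export
simulationConfig <- function(nChannels = 61, fs = 256, nTrialsPerClass = 20,
                             trialLength = 5, fixation = 3, restLength = 180,
                             restTrials = 20, restTrialLength = 8,
                             schedule = couplingSchedule(), snrDb = 10,
                             seed = 1, bands = bandTable()) {
  if (fs <= 2 * max(bands$high))
    stop(sprintf("fs = %g Hz must exceed twice the highest band edge (%g Hz)",
                 fs, max(bands$high)))
  labels <- montageLabels(nChannels)
  ent <- schedule$entries
  if (nrow(ent)) {
    refd <- unique(c(ent$chA, ent$chB))
    miss <- setdiff(refd, labels)
    if (length(miss))
      stop("schedule references unknown channels: ",
           paste(miss, collapse = ", "))
    if (any(ent$chA == ent$chB))
      stop("schedule pairs must reference two distinct channels")
    if (any(ent$from < -fixation | ent$to > trialLength))
      stop(sprintf("coupling windows must lie inside [-%g, %g] s around the cue",
                   fixation, trialLength))
    unk <- setdiff(unique(ent$band), bands$band)
    if (length(unk)) stop("schedule references unknown bands: ",
                          paste(unk, collapse = ", "))
  }
  structure(list(nChannels = nChannels, fs = fs,
                 nTrialsPerClass = nTrialsPerClass, trialLength = trialLength,
                 fixation = fixation, restLength = restLength,
                 restTrials = restTrials, restTrialLength = restTrialLength,
                 schedule = schedule, snrDb = snrDb, seed = seed,
                 bands = bands, channels = labels),
            class = "simulationConfig")
}

# 1/f^a-shaped Gaussian noise, one channel, unit variance.
pinkNoise <- function(n, exponent) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(1, seq_len(n - 1))          # avoid DC blow-up
  f <- pmin(f, n - f + 1)            # two-sided frequency index
  shape <- 1 / f^(exponent / 2)
  x <- Re(fft(X * shape, inverse = TRUE) / n)
  x / sd(x)
}

# Band-limited analytic Gaussian process: complex signal whose spectrum is
# confined to [low, high] Hz (positive frequencies only, so Re() is the real
# oscillation and Arg() its Hilbert phase). Unit variance of the real part.
bandNoise <- function(n, fs, low, high) {
  freqs <- (seq_len(n) - 1L) * fs / n
  idx <- which(freqs >= low & freqs <= high & freqs <= fs / 2)
  X <- complex(length.out = n)
  X[idx] <- complex(real = rnorm(length(idx)), imaginary = rnorm(length(idx)))
  x <- fft(X, inverse = TRUE) / n
  x / sd(Re(x))
}

# Core generator: continuous multichannel signal of `nsamp` samples with the
# scheduled couplings planted at the given event onsets/classes.
synthSignal <- function(config, nsamp, events, seed) {
  nch <- config$nChannels
  fs <- config$fs
  bands <- config$bands
  sched <- config$schedule
  nBands <- nrow(bands)
  nEv <- nrow(events)
  seeds <- subSeeds(seed, 1L + nBands + nBands * max(nEv, 1L))
  total <- matrix(0, nch, nsamp)
  rampLen <- round(0.1 * fs)
  for (b in seq_len(nBands)) {
    lo <- bands$low[b]; hi <- bands$high[b]
    set.seed(seeds[1L + b])
    A <- t(vapply(seq_len(nch), function(ch) bandNoise(nsamp, fs, lo, hi),
                  complex(nsamp)))
    comp <- Re(A)
    ent <- sched$entries[sched$entries$band == bands$band[b], , drop = FALSE]
    if (nrow(ent) && nEv) {
      for (ev in seq_len(nEv)) {
        set.seed(seeds[1L + nBands + (b - 1L) * nEv + ev])
        for (e in seq_len(nrow(ent))) {
          if (ent$class[e] != events$label[ev]) next
          from <- round((events$onset[ev] + ent$from[e]) * fs) + 1L
          to <- round((events$onset[ev] + ent$to[e]) * fs)
          if (from < 1L || to > nsamp) next
          win <- from:to
          wl <- length(win)
          latent <- bandNoise(wl, fs, lo, hi)
          ramp <- rep(1, wl)
          rl <- min(rampLen, floor(wl / 2))
          if (rl > 0) {
            edge <- (1 - cos(pi * seq_len(rl) / rl)) / 2
            ramp[seq_len(rl)] <- edge
            ramp[wl - rl + seq_len(rl)] <- rev(edge)
          }
          kap <- ent$kappa[e] * ramp
          for (ch in c(ent$chA[e], ent$chB[e])) {
            ci <- match(ch, config$channels)
            jit <- if (sched$jitterSd > 0)
              rnorm(wl, 0, sched$jitterSd) else rep(0, wl)
            # unit-power mixture: coupling must alter phase relations only,
            # not band amplitude (an amplitude dip would make every pair
            # touching a coupled channel class-informative)
            norm <- sqrt((1 - kap)^2 + kap^2)
            comp[ci, win] <- Re(((1 - kap) * A[ci, win] +
                                   kap * latent * exp(1i * jit)) / norm)
          }
        }
      }
    }
    total <- total + comp
  }
  set.seed(seeds[1L])
  oscPower <- rowMeans(total^2)
  noiseScale <- sqrt(oscPower / 10^(config$snrDb / 10))
  for (ch in seq_len(nch))
    total[ch, ] <- total[ch, ] +
      noiseScale[ch] * pinkNoise(nsamp, sched$noiseExponent)
  total
}

#' Simulate a continuous recording with planted phase couplings
#'
#' Generates a seeded multichannel recording: per channel, one narrowband
#' oscillation per rhythm (a band-limited Gaussian process with spectrum
#' confined to the band's edges) plus 1/f background noise at the configured
#' SNR. Wherever the coupling schedule applies, the scheduled pair shares a
#' latent band-limited oscillation (plus per-channel Gaussian phase jitter)
#' with mixing weight kappa, producing event-locked, class-conditioned phase
#' locking. Bit-identical output for identical configurations and seeds.
#'
#' @param config a [simulationConfig()].
#' @param kind \code{"mi"} for the cued motor-imagery session (trials =
#'   fixation + imagery blocks, with one event per cue) or \code{"rest"}
#'   for the un-cued baseline recording.
#' @return an \linkS4class{EEGRecording}; for \code{kind = "mi"} its events
#'   mark the cue onsets with class labels.
#' @examples
#' cfg <- simulationConfig(nChannels = 4, nTrialsPerClass = 2,
#'                         restLength = 16, restTrials = 2, seed = 7)
#' rec <- simulateRecording(cfg)
#' @export
simulateRecording <- function(config, kind = c("mi", "rest")) {
  stopifnot(inherits(config, "simulationConfig"))
  kind <- match.arg(kind)
  fs <- config$fs
  if (kind == "mi") {
    block <- config$fixation + config$trialLength
    nTrials <- 2L * config$nTrialsPerClass
    set.seed(subSeeds(config$seed, 1L))
    classes <- sample(rep(c("left", "right"), config$nTrialsPerClass))
    events <- data.frame(onset = (seq_len(nTrials) - 1L) * block +
                           config$fixation,
                         label = classes, stringsAsFactors = FALSE)
    nsamp <- round(nTrials * block * fs)
    sig <- synthSignal(config, nsamp, events, seed = config$seed + 1L)
  } else {
    events <- data.frame(onset = numeric(), label = character(),
                         stringsAsFactors = FALSE)
    nsamp <- round(config$restLength * fs)
    sig <- synthSignal(config, nsamp, events, seed = config$seed + 2L)
  }
  rownames(sig) <- config$channels
  new("EEGRecording", signal = sig, fs = fs, channels = config$channels,
      events = events)
}

#' Generate the full synthetic study dataset
#'
#' Simulates the cued motor-imagery session and the rest recording and cuts
#' wideband trial sets: \code{nTrialsPerClass} trials for each imagery class
#' and \code{restTrials} non-overlapping baseline trials. The ground-truth
#' schedule travels with the dataset so recovery tests can check selections
#' against the planted couplings.
#'
#' @param config a [simulationConfig()].
#' @return a list of class \code{plvStudy}: \code{mi} and \code{rest}
#'   recordings, wideband \code{left}, \code{right}, \code{rest} trial sets,
#'   the \code{schedule} ground truth and the \code{config}.
#' @export
makeStudyDataset <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  if (config$restTrials * config$restTrialLength > config$restLength)
    stop(sprintf("rest recording too short: %d x %g s needed, %g s configured",
                 config$restTrials, config$restTrialLength,
                 config$restLength))
  mi <- simulateRecording(config, "mi")
  rest <- simulateRecording(config, "rest")
  trials <- segmentAndRereference(mi, window = c(0, config$trialLength))
  keepL <- trialLabels(trials) == "left"
  left <- new("TrialSet", data = trials@data[, , keepL, drop = FALSE],
              labels = trials@labels[keepL], fs = trials@fs,
              channels = trials@channels, band = NA_character_, t0 = 0)
  right <- new("TrialSet", data = trials@data[, , !keepL, drop = FALSE],
               labels = trials@labels[!keepL], fs = trials@fs,
               channels = trials@channels, band = NA_character_, t0 = 0)
  restSet <- segmentRest(rest, n = config$restTrials,
                         length = config$restTrialLength)
  structure(list(mi = mi, rest = rest, left = left, right = right,
                 rest_trials = restSet, schedule = config$schedule,
                 config = config),
            class = "plvStudy")
}

#' Band-limited, re-referenced trial sets of a study dataset
#'
#' Applies the standard pre-processing chain to a synthetic (or loaded)
#' study: wideband 0.5-45 Hz zero-phase filtering of the continuous
#' recordings, bad-channel removal, average re-referencing, band-splitting
#' into the requested rhythm, and epoching. Filtering always precedes
#' epoching to keep edge transients outside the trials; re-referencing is
#' done once on the wideband signal before band-splitting.
#'
#' @param study a \code{plvStudy} from [makeStudyDataset()].
#' @param band band name; \code{NULL} keeps the wideband signal.
#' @param window epoch window in seconds relative to the cue (default the
#'   imagery interval \code{c(0, trialLength)}); use a negative start (e.g.
#'   \code{c(-3, 5)}) for streaming analyses needing pre-onset context.
#' @param badChannels channel labels to drop.
#' @return list with band-limited \code{left}, \code{right} and \code{rest}
#'   \linkS4class{TrialSet}s.
#' @export
studyTrialSets <- function(study, band = NULL, window = NULL,
                           badChannels = character()) {
  stopifnot(inherits(study, "plvStudy"))
  cfg <- study$config
  if (is.null(window)) window <- c(0, cfg$trialLength)
  wide <- c(0.5, min(45, cfg$fs / 2 - 1))
  prep <- function(rec) {
    rec <- bandpassFilter(rec, wide)
    rec <- averageReference(rec, badChannels)
    if (!is.null(band)) rec <- bandpassFilter(rec, band, bands = cfg$bands)
    rec
  }
  tag <- if (is.null(band)) NA_character_ else band
  mi <- segmentAndRereference(prep(study$mi), window = window, band = tag)
  keepL <- trialLabels(mi) == "left"
  subset <- function(ts, keep) new("TrialSet",
    data = ts@data[, , keep, drop = FALSE], labels = ts@labels[keep],
    fs = ts@fs, channels = ts@channels, band = ts@band, t0 = ts@t0)
  restSet <- segmentRest(prep(study$rest), n = cfg$restTrials,
                         length = cfg$restTrialLength, band = tag)
  list(left = subset(mi, keepL), right = subset(mi, !keepL),
       rest = restSet)
}
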