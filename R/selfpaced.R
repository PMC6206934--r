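#' @include ensemble.R synthdata.R
NULL

# Restrict a ConnectivitySequence to a subset of window positions.
sliceSequence <- function(s, cols) {
  new("ConnectivitySequence", vecs = s@vecs[, cols, drop = FALSE],
      step = s@step, window = s@window, band = s@band,
      times = s@times[cols], t0 = s@t0, channels = s@channels)
}

#' Streaming connectivity data for self-paced decoding
#'
#' Prepares, for one band, everything the self-paced pipeline consumes:
#' high-resolution (default 20 ms step) connectivity sequences over 8 s
#' epochs — MI trials cut with their fixation as pre-onset context
#' (\code{[-fixation, trialLength]}) and rest trials as baseline — plus the
#' post-onset window positions used for training the latency-specific
#' decoders.
#'
#' @param study a \code{plvStudy} from [makeStudyDataset()].
#' @param band band name.
#' @param step window step in seconds (default 0.02 for streaming).
#' @param badChannels channel labels to drop.
#' @return list: \code{left}, \code{right}, \code{rest} (lists of
#'   \linkS4class{ConnectivitySequence}), \code{trainCols} (post-onset
#'   column indices), \code{step}.
#' @export
selfPacedData <- function(study, band, step = 0.02,
                          badChannels = character()) {
  cfg <- study$config
  sets <- studyTrialSets(study, band = band,
                         window = c(-cfg$fixation, cfg$trialLength),
                         badChannels = badChannels)
  left <- trialSequences(sets$left, step = step)
  right <- trialSequences(sets$right, step = step)
  rest <- trialSequences(sets$rest, step = step)
  times <- left[[1]]@times
  trainCols <- which(times >= cfg$fixation - 1e-9)
  # report the effective step (windows advance by whole samples)
  list(left = left, right = right, rest = rest, trainCols = trainCols,
       step = left[[1]]@step)
}

#' Train the SVM-switch on ensemble-readout segments
#'
#' Second learning stage of the self-paced scheme: fixed-width (default
#' 0.5 s) segments of the classification-index traces form the training
#' set — MI-event segments drawn from the designated post-onset interval of
#' the MI traces (\code{nMiSegments} evenly spaced per trial), baseline
#' segments drawn evenly across the rest traces without interval
#' restriction, in equal total number. A radial-basis-kernel binary SVM
#' with probability outputs is fitted on the raw segment samples.
#'
#' @param miReadouts list of \code{ensembleReadout} for the MI training
#'   trials (both directions; the switch is direction-agnostic).
#' @param restReadouts list of \code{ensembleReadout} for the rest training
#'   trials.
#' @param width segment width in seconds (default 0.5).
#' @param interval onset-relative interval (seconds) MI segments are drawn
#'   from (default 0.2 to 2.0, the readout's peak region).
#' @param nMiSegments MI segments per trial (default 5).
#' @param threshold detection confidence threshold stored on the model.
#' @details Baseline-state segments are drawn in equal total number to the
#'   MI segments, half from the rest traces (anywhere) and half from the
#'   pre-cue fixation portion of the MI traces (segments ending before the
#'   onset), so that the switch sees the baseline state both in isolation
#'   and as it appears immediately before an event. If the traces offer no
#'   pre-onset span, all baseline segments come from rest.
#' @return a \linkS4class{SwitchModel}.
#' @export
trainSwitch <- function(miReadouts, restReadouts, width = 0.5,
                        interval = c(0.2, 2.0), nMiSegments = 5,
                        threshold = 0.5) {
  step <- miReadouts[[1]]$step
  segLen <- round(width / step)
  if (diff(interval) < width)
    stop("MI-segment interval shorter than the segment width")
  segAt <- function(trace, idx) trace[idx:(idx + segLen - 1L)]
  miSeg <- list()
  preSeg <- list()
  for (r in miReadouts) {
    if (length(r$z) < segLen) stop("readout trace shorter than a segment")
    starts <- seq(interval[1], interval[2] - width,
                  length.out = nMiSegments)
    for (s in starts) {
      idx <- which.min(abs(r$onsetTimes - s))
      idx <- min(max(idx, 1L), length(r$z) - segLen + 1L)
      miSeg[[length(miSeg) + 1L]] <- segAt(r$z, idx)
    }
    # baseline-state candidates: segments ending before the cue
    preMax <- sum(r$onsetTimes < -width) - 1L
    if (preMax >= 1L) {
      idxs <- unique(round(seq(1L, preMax,
                               length.out = min(nMiSegments, preMax))))
      for (idx in idxs)
        preSeg[[length(preSeg) + 1L]] <- segAt(r$z, idx)
    }
  }
  nBase <- length(miSeg)
  nPre <- min(length(preSeg), floor(nBase / 2))
  if (nPre > 0)
    preSeg <- preSeg[unique(round(seq(1L, length(preSeg),
                                      length.out = nPre)))]
  else preSeg <- list()
  nFromRest <- nBase - length(preSeg)
  perRest <- ceiling(nFromRest / length(restReadouts))
  baseSeg <- list()
  for (r in restReadouts) {
    idxs <- unique(round(seq(1L, length(r$z) - segLen + 1L,
                             length.out = perRest)))
    for (idx in idxs)
      baseSeg[[length(baseSeg) + 1L]] <- segAt(r$z, idx)
  }
  baseSeg <- c(baseSeg[seq_len(min(length(baseSeg), nFromRest))], preSeg)
  X <- rbind(do.call(rbind, miSeg), do.call(rbind, baseSeg))
  y <- factor(rep(c("mi", "baseline"), c(length(miSeg), length(baseSeg))),
              levels = c("baseline", "mi"))
  fit <- e1071::svm(X, y, kernel = "radial", probability = TRUE)
  new("SwitchModel", fit = fit, width = width, step = step,
      threshold = threshold,
      segmentCounts = c(mi = length(miSeg), baseline = length(baseSeg)))
}

#' Trigger-free event detection on a streaming readout
#'
#' Slides 0.5 s segments along the classification-index trace, scores each
#' with the SVM-switch, and flags an MI event wherever the switch confidence
#' exceeds the threshold; consecutive supra-threshold positions merge into a
#' single detection whose direction is the sign of the classification index
#' at the flag. A genuine imagery event holds the readout pattern for on
#' the order of a second, so supra-threshold flickers shorter than
#' \code{minDuration} (default: one segment width) are discarded — the same
#' temporal-persistence principle the coupling screening applies at the
#' feature level.
#'
#' @param readout an \code{ensembleReadout}.
#' @param switch a \linkS4class{SwitchModel}.
#' @param threshold detection threshold; defaults to the model's.
#' @param minDuration minimum duration (seconds) a supra-threshold run must
#'   sustain to count as a detection; defaults to the switch segment width.
#' @return data.frame with one row per detection: \code{time} (hypothesized
#'   onset, seconds relative to the epoch's event onset), \code{direction}
#'   (+1 right / -1 left) and \code{confidence} (peak switch confidence of
#'   the merged run).
#' @export
streamDecode <- function(readout, switch, threshold = NULL,
                         minDuration = NULL) {
  if (is.null(threshold)) threshold <- switch@threshold
  if (is.null(minDuration)) minDuration <- switch@width
  segLen <- round(switch@width / switch@step)
  z <- readout$z
  nSeg <- length(z) - segLen + 1L
  if (nSeg < 1L)
    return(data.frame(time = numeric(), direction = numeric(),
                      confidence = numeric()))
  X <- t(vapply(seq_len(nSeg), function(s) z[s:(s + segLen - 1L)],
                numeric(segLen)))
  pr <- predict(switch@fit, X, probability = TRUE)
  conf <- attr(pr, "probabilities")[, "mi"]
  supra <- conf > threshold
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  minRun <- max(1L, round(minDuration / switch@step))
  det <- which(r$values & r$lengths >= minRun)
  if (!length(det))
    return(data.frame(time = numeric(), direction = numeric(),
                      confidence = numeric()))
  rows <- lapply(det, function(k) {
    seg <- starts[k]:ends[k]
    peak <- seg[which.min(-conf[seg])]
    zmean <- mean(z[peak:(peak + segLen - 1L)])
    data.frame(time = readout$onsetTimes[peak],
               direction = sign(zmean), confidence = conf[peak])
  })
  do.call(rbind, rows)
}

#' Two-stage self-paced training
#'
#' Runs the full data-learning process on a training split: (1) coupling
#' selection by [bootstrapSelect()] and training/selection of the
#' latency-specific SVMs into an ensemble, using only the post-onset MI
#' sequences; (2) ensemble readout of all training trials (MI and rest) and
#' training of the SVM-switch on readout segments.
#'
#' @param data streaming data from [selfPacedData()].
#' @param trainL,trainR,trainRest integer indices of the training trials in
#'   each class.
#' @param nBoot,nRand screening parameters (defaults 30 / 100).
#' @param seed seed for the screening resampling streams.
#' @param switchInterval MI-segment interval passed to [trainSwitch()].
#' @param threshold switch detection threshold.
#' @param maxLagSeconds lag span allowed for ensemble members (default 2 s:
#'   early members keep the readout trace long and the response speedy).
#' @return list: \code{screening}, \code{timeResolved}, \code{ensemble},
#'   \code{switch}.
#' @export
trainSelfPaced <- function(data, trainL, trainR, trainRest, nBoot = 30,
                           nRand = 100, seed = 1,
                           switchInterval = c(0.2, 2.0), threshold = 0.5,
                           maxLagSeconds = 2) {
  slicedL <- lapply(data$left[trainL], sliceSequence, cols = data$trainCols)
  slicedR <- lapply(data$right[trainR], sliceSequence, cols = data$trainCols)
  scr <- bootstrapSelect(slicedL, slicedR, nBoot = nBoot, nRand = nRand,
                         step = data$step, seed = seed)
  trs <- timeResolvedSvms(slicedL, slicedR, selectedPairs(scr))
  ens <- buildEnsemble(trs$accuracy, trs$bank, step = data$step,
                       window = trs$window, maxLagSeconds = maxLagSeconds)
  miReadouts <- lapply(c(data$left[trainL], data$right[trainR]),
                       ensembleReadout, ensemble = ens)
  restReadouts <- lapply(data$rest[trainRest], ensembleReadout,
                         ensemble = ens)
  sw <- trainSwitch(miReadouts, restReadouts, interval = switchInterval,
                    threshold = threshold)
  list(screening = scr, timeResolved = trs, ensemble = ens, switch = sw)
}

#' Score self-paced detections on held-out trials
#'
#' Feeds each test trial's streaming readout through the switch and counts
#' false positives (any detection in a rest trial, or a detection outside
#' the valid onset window in an MI trial) and false negatives (an MI trial
#' with no detection inside the valid window). Rates are referenced to the
#' total number of test trials.
#'
#' @param model output of [trainSelfPaced()].
#' @param data streaming data from [selfPacedData()].
#' @param testL,testR,testRest test-trial indices per class.
#' @param validWindow onset-relative window (seconds) in which an MI
#'   detection counts as correct.
#' @return list: \code{fp}, \code{fn} (rates in [0, 1]), \code{fpCount},
#'   \code{fnCount}, \code{nTrials}.
#' @export
evaluateSelfPaced <- function(model, data, testL, testR, testRest,
                              validWindow = c(-0.5, 2.5)) {
  decodeAll <- function(seqs) lapply(seqs, function(s)
    streamDecode(ensembleReadout(s, model$ensemble), model$switch))
  detL <- decodeAll(data$left[testL])
  detR <- decodeAll(data$right[testR])
  detRest <- decodeAll(data$rest[testRest])
  fp <- 0L; fn <- 0L
  for (d in c(detL, detR)) {
    hit <- nrow(d) > 0 && any(d$time >= validWindow[1] &
                                d$time <= validWindow[2])
    false <- nrow(d) > 0 && any(d$time < validWindow[1] |
                                  d$time > validWindow[2])
    if (!isTRUE(hit)) fn <- fn + 1L
    if (false) fp <- fp + 1L
  }
  for (d in detRest) if (nrow(d) > 0) fp <- fp + 1L
  n <- length(detL) + length(detR) + length(detRest)
  list(fp = fp / n, fn = fn / n, fpCount = fp, fnCount = fn, nTrials = n)
}

#' Monte-Carlo cross-validated self-paced evaluation
#'
#' Repeats the full two-stage pipeline over randomized 10-per-class
#' train/test partitions: per split, coupling selection, the
#' latency-specific SVM bank, the ensemble and the switch are all refit on
#' the training trials, and FP/FN rates are counted on the held-out trials.
#' Rates are averaged across splits and reported as percentages.
#'
#' @param data streaming data from [selfPacedData()].
#' @param nSplits number of Monte-Carlo splits (default 100).
#' @param nTrain training trials per class (default 10).
#' @param seed master seed; split partitions and all refits derive from it.
#' @param nBoot,nRand screening parameters.
#' @param validWindow passed to [evaluateSelfPaced()].
#' @return list: \code{fp}, \code{fn} (mean percentages), \code{perSplit}
#'   data.frame.
#' @export
monteCarloSelfPaced <- function(data, nSplits = 100, nTrain = 10, seed = 1,
                                nBoot = 30, nRand = 100,
                                validWindow = c(-0.5, 2.5)) {
  nL <- length(data$left); nR <- length(data$right)
  nRest <- length(data$rest)
  if (min(nL, nR, nRest) <= nTrain)
    stop("insufficient trials for a ", nTrain, "-per-class training split")
  seeds <- subSeeds(seed, nSplits)
  rows <- vector("list", nSplits)
  for (s in seq_len(nSplits)) {
    set.seed(seeds[s])
    trL <- sample.int(nL, nTrain); trR <- sample.int(nR, nTrain)
    trB <- sample.int(nRest, nTrain)
    model <- trainSelfPaced(data, trL, trR, trB, nBoot = nBoot,
                            nRand = nRand, seed = seeds[s])
    ev <- evaluateSelfPaced(model, data, setdiff(seq_len(nL), trL),
                            setdiff(seq_len(nR), trR),
                            setdiff(seq_len(nRest), trB),
                            validWindow = validWindow)
    rows[[s]] <- data.frame(split = s, fp = ev$fp, fn = ev$fn)
  }
  perSplit <- do.call(rbind, rows)
  list(fp = 100 * mean(perSplit$fp), fn = 100 * mean(perSplit$fn),
       perSplit = perSplit)
}
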