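#' @include AllGenerics.R
NULL

#' @describeIn EEGRecording sampling rate in Hz.
#' @param x,object an \code{EEGRecording}.
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @describeIn EEGRecording channel labels.
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channels)

#' @describeIn EEGRecording event markers (onset seconds + class label).
#' @export
setMethod("eventTable", "EEGRecording", function(x) x@events)

#' @describeIn TrialSet sampling rate in Hz.
#' @param x,object a \code{TrialSet}.
#' @export
setMethod("samplingRate", "TrialSet", function(x) x@fs)

#' @describeIn TrialSet retained channel labels.
#' @export
setMethod("channelNames", "TrialSet", function(x) x@channels)

#' @describeIn TrialSet number of trials.
#' @export
setMethod("trialCount", "TrialSet", function(x) dim(x@data)[3L])

#' @describeIn TrialSet per-trial class labels.
#' @export
setMethod("trialLabels", "TrialSet", function(x) x@labels)

#' Extract one trial epoch
#'
#' @param x a \linkS4class{TrialSet}.
#' @param i trial index.
#' @return channels x samples numeric matrix.
#' @export
getTrial <- function(x, i) {
  stopifnot(is(x, "TrialSet"), i >= 1, i <= trialCount(x))
  m <- x@data[, , i, drop = FALSE]
  dim(m) <- dim(x@data)[1:2]
  rownames(m) <- x@channels
  m
}

#' @describeIn ConnectivityPattern row-major upper triangle of W.
#' @export
setMethod("vecW", "ConnectivityPattern", function(x) {
  x@W[upper.tri(x@W)][pairIndexMap(nrow(x@W))$utPos]
})

#' @describeIn ConnectivitySequence matrix of vec(W[tau]) columns.
#' @export
setMethod("vecW", "ConnectivitySequence", function(x) x@vecs)

#' PLV adjacency matrix accessor
#' @param x a \linkS4class{ConnectivityPattern}.
#' @return symmetric matrix of PLV values.
#' @export
plvAdjacency <- function(x) {
  stopifnot(is(x, "ConnectivityPattern"))
  x@W
}

#' Selected pair indices of a screening result
#' @param x a \linkS4class{ScreeningResult}.
#' @return integer vector of vec(W) positions.
#' @export
selectedPairs <- function(x) {
  stopifnot(is(x, "ScreeningResult"))
  x@selected
}

#' Consistency profile accessor
#' @param x a \linkS4class{ScreeningResult}.
#' @return numeric per-pair persistence profile.
#' @export
pairProfile <- function(x) {
  stopifnot(is(x, "ScreeningResult"))
  x@profile
}

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@signal), ncol(object@signal), object@fs,
              ncol(object@signal) / object@fs))
  if (nrow(object@events))
    cat(sprintf("  events: %d (%s)\n", nrow(object@events),
                paste(sprintf("%s=%d", names(table(object@events$label)),
                              as.integer(table(object@events$label))),
                      collapse = ", ")))
  else cat("  events: none\n")
})

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("TrialSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[3], d[1], d[2], object@fs))
  cat(sprintf("  band: %s; t0 = %g s; labels: %s\n",
              ifelse(is.na(object@band), "wideband", object@band), object@t0,
              paste(sprintf("%s=%d", names(table(object@labels)),
                            as.integer(table(object@labels))),
                    collapse = ", ")))
})

setMethod("show", "ConnectivityPattern", function(object) {
  n <- nrow(object@W)
  cat(sprintf("ConnectivityPattern: %d sensors, %d pairs, band %s, window [%g, %g] s\n",
              n, n * (n - 1) / 2, ifelse(is.na(object@band), "?", object@band),
              object@window[1], object@window[2]))
  cat(sprintf("  PLV range (off-diagonal): [%.3f, %.3f]\n",
              min(object@W[upper.tri(object@W)]),
              max(object@W[upper.tri(object@W)])))
})

setMethod("show", "ConnectivitySequence", function(object) {
  cat(sprintf(
    "ConnectivitySequence: %d pairs x %d windows (T = %g s, step = %g s, band %s)\n",
    nrow(object@vecs), ncol(object@vecs), object@window, object@step,
    ifelse(is.na(object@band), "?", object@band)))
})

setMethod("show", "ScreeningResult", function(object) {
  cat(sprintf("ScreeningResult: %d pairs x %d latencies\n",
              nrow(object@scores), ncol(object@scores)))
  if (!is.na(object@threshold))
    cat(sprintf("  threshold (99.9%%, %d permutations): %.3f\n",
                object@nRand, object@threshold))
  if (object@nBoot > 0)
    cat(sprintf("  bootstrap resamples: %d\n", object@nBoot))
  cat(sprintf("  selected pairs: %d\n", length(object@selected)))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: M = %d members over %d couplings (step %g s)\n",
              length(object@members), length(object@features), object@step))
  cat(sprintf("  lags (window index): %s\n",
              paste(object@lags, collapse = ", ")))
  cat(sprintf("  member LOOCV accuracy: %s\n",
              paste(sprintf("%.2f", object@accuracy), collapse = ", ")))
})

setMethod("show", "SwitchModel", function(object) {
  cat(sprintf("SwitchModel: RBF segment classifier (width %g s, step %g s, threshold %.2f)\n",
              object@width, object@step, object@threshold))
})
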