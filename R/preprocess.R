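#' @include utils.R bands.R
NULL

# Zero-phase (forward-backward) IIR filtering of one channel with odd-reflect
# padding of three filter lengths at each end, so that short records are not
# contaminated by the filter's startup transient.
zeroPhaseFilter <- function(x, b, a) {
  n <- length(x)
  npad <- min(3L * (length(b) + length(a)), n - 1L)
  front <- 2 * x[1] - x[(npad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - npad)]
  xx <- c(front, x, back)
  y <- as.numeric(signal::filter(b, a, xx))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(npad + 1):(npad + n)]
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Filters every channel of a continuous recording with a third-order
#' Butterworth band-pass applied in zero-phase (forward-backward) mode.
#' Filtering is meant to be applied to the continuous recording, before
#' epoching, to keep edge transients away from the trials.
#'
#' @param recording an \linkS4class{EEGRecording} (or a channels x samples
#'   matrix, in which case \code{fs} must be given).
#' @param band band name (see [bandTable()]) or numeric \code{c(low, high)}
#'   edges in Hz.
#' @param order filter order (default 3).
#' @param fs sampling rate, only needed for matrix input.
#' @param bands band table for name lookup.
#' @return object of the same kind as the input, filtered; for an
#'   \code{EEGRecording} the band is available downstream via the trial sets
#'   cut from it.
#' @examples
#' fs <- 256
#' x <- matrix(sin(2 * pi * 9 * seq(0, 2, by = 1 / fs)), nrow = 1)
#' y <- bandpassFilter(x, c(8, 10), fs = fs)
#' @export
bandpassFilter <- function(recording, band, order = 3, fs = NULL,
                           bands = bandTable()) {
  edges <- bandEdges(band, bands)
  if (is(recording, "EEGRecording")) {
    sig <- recording@signal
    fs <- recording@fs
  } else {
    sig <- recording
    if (is.null(fs)) stop("fs required for matrix input")
  }
  if (edges[2] >= fs / 2)
    stop(sprintf("band edge %g Hz at or above Nyquist (%g Hz)",
                 edges[2], fs / 2))
  bt <- signal::butter(order, edges / (fs / 2), type = "pass")
  out <- t(apply(sig, 1, zeroPhaseFilter, b = bt$b, a = bt$a))
  if (is(recording, "EEGRecording")) {
    recording@signal <- out
    recording
  } else out
}

#' Average re-referencing over good channels
#'
#' Subtracts, at each sample, the instantaneous mean over the retained
#' ("good") channels. Idempotent: applying it twice equals applying it once.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param badChannels character vector of channel labels to drop before
#'   re-referencing (the study's visual/spectral bad-channel marking is a
#'   manual step; see [flagBadChannels()] for a convenience heuristic).
#' @return re-referenced \code{EEGRecording} containing only good channels.
#' @export
averageReference <- function(recording, badChannels = character()) {
  stopifnot(is(recording, "EEGRecording"))
  keep <- !(recording@channels %in% badChannels)
  if (!any(keep)) stop("all channels marked bad")
  sig <- recording@signal[keep, , drop = FALSE]
  sig <- sweep(sig, 2, colMeans(sig))
  new("EEGRecording", signal = sig, fs = recording@fs,
      channels = recording@channels[keep], events = recording@events)
}

#' Heuristic bad-channel flagger
#'
#' Flags channels whose log-variance deviates from the montage median by more
#' than \code{z} robust z-scores. Provided as a convenience only; the
#' authoritative bad-channel list is supplied by the analyst.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param z robust z-score cutoff (default 4).
#' @return character vector of flagged channel labels (possibly empty).
#' @export
flagBadChannels <- function(recording, z = 4) {
  stopifnot(is(recording, "EEGRecording"))
  v <- log(apply(recording@signal, 1, var) + .Machine$double.eps)
  med <- median(v)
  s <- mad(v)
  if (s == 0) return(character())
  recording@channels[abs(v - med) / s > z]
}

#' Epoching with average re-referencing
#'
#' Cuts per-event epochs out of a (already filtered) continuous recording,
#' drops bad channels, and re-references each sample by the instantaneous
#' mean over the good channels.
#'
#' @param recording an \linkS4class{EEGRecording} whose events mark trial
#'   onsets.
#' @param window numeric \code{c(from, to)} in seconds relative to each event
#'   onset (default \code{c(0, 5)}: the imagery interval).
#' @param badChannels channel labels to drop.
#' @param band band tag to record on the resulting trial set (metadata only).
#' @return a \linkS4class{TrialSet} with one epoch per event and
#'   \code{t0 = window[1]}.
#' @export
segmentAndRereference <- function(recording, window = c(0, 5),
                                  badChannels = character(),
                                  band = NA_character_) {
  stopifnot(is(recording, "EEGRecording"))
  ev <- recording@events
  if (nrow(ev) == 0) stop("recording has no events to segment on")
  rec <- averageReference(recording, badChannels)
  fs <- rec@fs
  nsamp <- ncol(rec@signal)
  wlen <- round((window[2] - window[1]) * fs)
  epochs <- array(0, dim = c(nrow(rec@signal), wlen, nrow(ev)))
  for (i in seq_len(nrow(ev))) {
    from <- round((ev$onset[i] + window[1]) * fs) + 1L
    to <- from + wlen - 1L
    if (from < 1L || to > nsamp)
      stop(sprintf("event %d window [%g, %g] s exceeds the recording", i,
                   ev$onset[i] + window[1], ev$onset[i] + window[2]))
    epochs[, , i] <- rec@signal[, from:to]
  }
  new("TrialSet", data = epochs, labels = as.character(ev$label), fs = fs,
      channels = rec@channels, band = band, t0 = window[1])
}

#' Cut a rest recording into consecutive baseline trials
#'
#' Splits an un-cued (resting-state) recording into consecutive,
#' non-overlapping trials of fixed length after dropping bad channels and
#' average re-referencing.
#'
#' @param recording an \linkS4class{EEGRecording} without (or ignoring)
#'   events.
#' @param n number of trials to extract.
#' @param length trial length in seconds (default 8).
#' @param badChannels channel labels to drop.
#' @param band band tag metadata.
#' @return a \linkS4class{TrialSet} of \code{n} trials labelled "rest".
#' @export
segmentRest <- function(recording, n = 20, length = 8,
                        badChannels = character(), band = NA_character_) {
  stopifnot(is(recording, "EEGRecording"))
  rec <- averageReference(recording, badChannels)
  fs <- rec@fs
  wlen <- round(length * fs)
  if (n * wlen > ncol(rec@signal))
    stop(sprintf("rest recording too short: %d x %g s needed, %.1f s available",
                 n, length, ncol(rec@signal) / fs))
  epochs <- array(0, dim = c(nrow(rec@signal), wlen, n))
  for (i in seq_len(n))
    epochs[, , i] <- rec@signal[, ((i - 1L) * wlen + 1L):(i * wlen)]
  new("TrialSet", data = epochs, labels = rep("rest", n), fs = fs,
      channels = rec@channels, band = band, t0 = 0)
}
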