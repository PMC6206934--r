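#' @include hilbert.R bands.R
NULL

#' Pair-to-position map for vec(W)
#'
#' Fixes the vectorization order of the upper triangle of a symmetric
#' connectivity matrix: pairs are scanned row-major, (1,2), (1,3), ...,
#' (1,N), (2,3), ..., (N-1,N). \code{utPos} gives, for each vec position,
#' the rank of that pair in R's column-major \code{upper.tri} order, so
#' that \code{ut[order(map$utPos)]} reorders a column-major upper-triangle
#' extraction into vec(W) order.
#'
#' @param n number of sensors.
#' @return data.frame with columns \code{i}, \code{j} (channel indices,
#'   i < j), \code{pair} (vec position) and \code{utPos}.
#' @examples
#' pairIndexMap(4)
#' @export
pairIndexMap <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(r) seq.int(r + 1L, n)))
  # column-major upper.tri rank of (i, j): entries of column j precede it
  utPos <- (j - 1L) * (j - 2L) / 2L + i
  data.frame(i = i, j = j, pair = seq_along(i), utPos = as.integer(utPos))
}

# Unit phasors of a phase matrix restricted to a sample window.
phasors <- function(phase, from, to) {
  exp(1i * phase[, from:to, drop = FALSE])
}

#' PLV connectivity matrix of one trial
#'
#' Computes the phase locking value between every pair of channels over one
#' integration window: the modulus of the time-averaged unit phasor of the
#' pairwise phase difference. All pairs are computed in a single pass by
#' accumulating the outer product of the per-sample unit phasors over time,
#' rather than looping over pairs.
#'
#' @param trial channels x samples matrix of one band-limited epoch, or a
#'   precomputed phase matrix (see \code{isPhase}).
#' @param t1,t2 integration window in seconds relative to epoch start;
#'   defaults to the full epoch.
#' @param fs sampling rate in Hz (needed when \code{t1}/\code{t2} are given).
#' @param band band tag recorded on the result.
#' @param channels channel labels.
#' @param isPhase set TRUE when \code{trial} already holds instantaneous
#'   phases.
#' @return a \linkS4class{ConnectivityPattern}.
#' @examples
#' fs <- 128; t <- seq(0, 2 - 1 / fs, by = 1 / fs)
#' x <- rbind(cos(2 * pi * 10 * t), cos(2 * pi * 10 * t + 1))
#' plvAdjacency(plvMatrix(x, fs = fs))[1, 2]  # constant lag -> 1
#' @export
plvMatrix <- function(trial, t1 = NULL, t2 = NULL, fs = NULL,
                      band = NA_character_, channels = character(),
                      isPhase = FALSE) {
  stopifnot(is.matrix(trial))
  nsamp <- ncol(trial)
  if (is.null(t1) && is.null(t2)) {
    from <- 1L; to <- nsamp
    if (is.null(fs)) fs <- 1
  } else {
    if (is.null(fs)) stop("fs required when a window is given")
    from <- round(t1 * fs) + 1L
    to <- round(t2 * fs)
    if (from < 1L || to > nsamp || to - from + 1L < 2L)
      stop("integration window outside the trial (or fewer than 2 samples)")
  }
  phase <- if (isPhase) trial else instantaneousPhase(trial)
  U <- phasors(phase, from, to)
  n <- to - from + 1L
  W <- Mod(U %*% Conj(t(U))) / n
  W[W > 1] <- 1  # guard rounding
  diag(W) <- 1
  W <- (W + t(W)) / 2
  if (!length(channels)) channels <- rownames(trial) %||% character()
  new("ConnectivityPattern", W = W, band = band,
      window = c((from - 1L) / fs, to / fs),
      channels = as.character(channels %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sliding-window PLV connectivity of one trial
#'
#' Derives the time-indexed sequence vec(W[tau]) by confining the PLV
#' integration to overlapping windows advanced by \code{step} seconds. The
#' window width follows the cycle criterion: \code{cycles} periods of the
#' band's lowest frequency (default 3). Phases are extracted once over the
#' full epoch and the per-pair phasor series is accumulated with cumulative
#' sums, so each window costs one subtraction per pair. Partial windows at
#' the trial end are discarded.
#'
#' @param trial channels x samples matrix of one band-limited epoch.
#' @param band band name or numeric edges; sets the cycle-criterion width.
#' @param step window step in seconds: 0.35 for cued decoding (default),
#'   0.02 for streaming/self-paced analysis.
#' @param fs sampling rate in Hz.
#' @param cycles cycle-criterion multiplier (default 3).
#' @param t0 epoch start relative to event onset, seconds (metadata).
#' @param channels channel labels.
#' @param bands band table for name lookup.
#' @return a \linkS4class{ConnectivitySequence}; \code{ncol(vecW(x))} equals
#'   \code{floor((L - T_window)/step) + 1} for an epoch of L seconds.
#' @export
slidingConnectivity <- function(trial, band, step = 0.35, fs,
                                cycles = 3, t0 = 0, channels = character(),
                                bands = bandTable()) {
  stopifnot(is.matrix(trial), step > 0)
  edges <- bandEdges(band, bands)
  Twin <- cycles / edges[1]
  L <- ncol(trial) / fs
  if (Twin > L)
    stop(sprintf("cycle-criterion window (%.3f s) exceeds the trial (%.3f s)",
                 Twin, L))
  wlen <- round(Twin * fs)
  slen <- round(step * fs)
  if (slen < 1L) stop("step below one sample")
  step <- slen / fs  # effective step: whole samples
  starts <- seq.int(1L, ncol(trial) - wlen + 1L, by = slen)
  phase <- instantaneousPhase(trial)
  nch <- nrow(trial)
  map <- pairIndexMap(nch)
  U <- exp(1i * phase)
  D <- U[map$i, , drop = FALSE] * Conj(U[map$j, , drop = FALSE])
  cs <- t(apply(D, 1, cumsum))
  ends <- starts + wlen - 1L
  sums <- cs[, ends, drop = FALSE] -
    cbind(if (starts[1] == 1L) 0 else NULL,
          cs[, starts[-1] - 1L, drop = FALSE])
  vecs <- Mod(sums) / wlen
  vecs[vecs > 1] <- 1
  bandTag <- if (is.character(band)) band else NA_character_
  if (!length(channels)) channels <- rownames(trial) %||% montageLabels(nch)
  new("ConnectivitySequence", vecs = vecs, step = step, window = Twin,
      band = bandTag, times = (starts - 1L) / fs, t0 = t0,
      channels = as.character(channels))
}

#' Static pattern matrix of a trial set
#'
#' Convenience: computes vec(W) for every trial of a band-limited
#' \linkS4class{TrialSet} over one integration window and stacks them as
#' rows (trials x pairs) — the feature matrix of the static decoding
#' scenario.
#'
#' @param trials a \linkS4class{TrialSet}.
#' @param t1,t2 integration window in seconds (defaults to the full epoch).
#' @return numeric matrix, trials x N_pairs.
#' @export
staticPatterns <- function(trials, t1 = NULL, t2 = NULL) {
  stopifnot(is(trials, "TrialSet"))
  n <- trialCount(trials)
  out <- NULL
  for (k in seq_len(n)) {
    p <- plvMatrix(getTrial(trials, k), t1 = t1, t2 = t2,
                   fs = trials@fs, band = trials@band,
                   channels = trials@channels)
    v <- vecW(p)
    if (is.null(out)) out <- matrix(0, n, length(v))
    out[k, ] <- v
  }
  out
}

#' Sliding-window sequences for every trial of a set
#'
#' @param trials a band-limited \linkS4class{TrialSet}.
#' @param step window step in seconds.
#' @param cycles cycle-criterion multiplier.
#' @param bands band table.
#' @return list of \linkS4class{ConnectivitySequence}, one per trial.
#' @export
trialSequences <- function(trials, step = 0.35, cycles = 3,
                           bands = bandTable()) {
  stopifnot(is(trials, "TrialSet"))
  if (is.na(trials@band))
    stop("trial set carries no band tag; band-filter it first")
  lapply(seq_len(trialCount(trials)), function(k)
    slidingConnectivity(getTrial(trials, k), band = trials@band, step = step,
                        fs = trials@fs, cycles = cycles, t0 = trials@t0,
                        channels = trials@channels, bands = bands))
}
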