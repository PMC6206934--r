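#' @import methods
NULL

#' EEGRecording: a continuous multichannel recording
#'
#' Container for a continuous multichannel EEG-like signal together with its
#' sampling rate, channel labels (10-10 montage order) and event markers.
#'
#' @slot signal numeric matrix, channels x samples (microvolt-scale units are
#'   assumed but not enforced).
#' @slot fs sampling rate in Hz.
#' @slot channels character vector of channel labels, one per signal row.
#' @slot events data.frame with columns \code{onset} (seconds from recording
#'   start) and \code{label} (\code{"left"}, \code{"right"} or \code{"rest"});
#'   may have zero rows for an un-cued recording.
#'
#' @seealso [simulateRecording()], [readRecording()], [segmentAndRereference()]
#' @export
setClass("EEGRecording",
  representation(signal = "matrix", fs = "numeric",
                 channels = "character", events = "data.frame"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@signal))
    msg <- c(msg, "signal must be a numeric matrix")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channels) != nrow(object@signal))
    msg <- c(msg, "one channel label per signal row required")
  if (anyDuplicated(object@channels))
    msg <- c(msg, "channel labels must be unique")
  if (nrow(object@events) > 0) {
    if (!all(c("onset", "label") %in% names(object@events)))
      msg <- c(msg, "events needs 'onset' and 'label' columns")
    else {
      dur <- ncol(object@signal) / object@fs
      if (any(object@events$onset < 0 | object@events$onset > dur))
        msg <- c(msg, "event onsets must lie inside the recording")
    }
  }
  if (length(msg)) msg else TRUE
})

#' TrialSet: epoched, optionally band-limited trials
#'
#' Epoched multichannel data with one class label per trial. All epochs share
#' the same channels-by-samples shape. A band tag records which rhythm the
#' epochs were filtered to (or \code{NA} for wideband data).
#'
#' @slot data numeric array, channels x samples x trials.
#' @slot labels character vector of per-trial class labels
#'   (\code{"left"}, \code{"right"}, \code{"rest"}).
#' @slot fs sampling rate in Hz.
#' @slot channels retained ("good") channel labels.
#' @slot band band tag (name from the band table) or \code{NA_character_}.
#' @slot t0 time of the first epoch sample relative to the event onset, in
#'   seconds (0 for epochs cut at the cue; negative when pre-onset context
#'   is included).
#'
#' @seealso [segmentAndRereference()], [studyTrialSets()]
#' @export
setClass("TrialSet",
  representation(data = "array", labels = "character", fs = "numeric",
                 channels = "character", band = "character", t0 = "numeric"))

setValidity("TrialSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a channels x samples x trials array")
  else {
    if (length(object@channels) != d[1L])
      msg <- c(msg, "channel labels must match first array dimension")
    if (length(object@labels) != d[3L])
      msg <- c(msg, "one label per trial required")
  }
  bad <- setdiff(unique(object@labels), c("left", "right", "rest"))
  if (length(bad))
    msg <- c(msg, paste0("unknown trial labels: ", paste(bad, collapse = ", ")))
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' ConnectivityPattern: a static PLV adjacency matrix
#'
#' Symmetric matrix of pairwise phase locking values over one integration
#' window, with unit diagonal. The economical description \code{vec(W)} is the
#' row-major upper triangle (pairs (1,2), (1,3), ..., (1,N), (2,3), ...),
#' exposed by [vecW()]; the pair-to-position map is [pairIndexMap()].
#'
#' @slot W symmetric numeric matrix of PLV in [0, 1], unit diagonal.
#' @slot band band tag or \code{NA_character_}.
#' @slot window numeric length-2 integration window (seconds, epoch-relative).
#' @slot channels channel labels for the matrix rows/columns.
#'
#' @seealso [plvMatrix()], [vecW()]
#' @export
setClass("ConnectivityPattern",
  representation(W = "matrix", band = "character", window = "numeric",
                 channels = "character"))

setValidity("ConnectivityPattern", function(object) {
  msg <- character()
  W <- object@W
  if (nrow(W) != ncol(W)) msg <- c(msg, "W must be square")
  tol <- 1e-8
  if (any(W < -tol | W > 1 + tol)) msg <- c(msg, "PLV entries must lie in [0, 1]")
  if (max(abs(W - t(W))) > 1e-8) msg <- c(msg, "W must be symmetric")
  if (max(abs(diag(W) - 1)) > 1e-8) msg <- c(msg, "W must have unit diagonal")
  if (length(object@channels) && length(object@channels) != nrow(W))
    msg <- c(msg, "channel labels must match matrix dimension")
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msg <- c(msg, "window must be (t1, t2) with t1 < t2")
  if (length(msg)) msg else TRUE
})

#' ConnectivitySequence: time-indexed connectivity patterns
#'
#' The sequence vec(W[tau]), tau = 1..N_tau, of one trial: each column holds
#' the vectorized upper triangle of the PLV matrix integrated over one
#' sliding-window position. The window width follows the cycle criterion
#' (3 cycles of the band's lowest frequency) and windows advance by
#' \code{step} seconds.
#'
#' @slot vecs numeric matrix, N_pairs x N_tau.
#' @slot step window step in seconds.
#' @slot window window width T_window in seconds.
#' @slot band band tag.
#' @slot times start time of each window, seconds from epoch start.
#' @slot t0 epoch start relative to event onset (seconds); see
#'   \linkS4class{TrialSet}.
#' @slot channels channel labels of the underlying trial.
#'
#' @seealso [slidingConnectivity()]
#' @export
setClass("ConnectivitySequence",
  representation(vecs = "matrix", step = "numeric", window = "numeric",
                 band = "character", times = "numeric", t0 = "numeric",
                 channels = "character"))

setValidity("ConnectivitySequence", function(object) {
  msg <- character()
  if (ncol(object@vecs) != length(object@times))
    msg <- c(msg, "one window start time per column required")
  n <- length(object@channels)
  if (n > 0 && nrow(object@vecs) != n * (n - 1) / 2)
    msg <- c(msg, "rows must equal N(N-1)/2 for N channels")
  if (object@step <= 0) msg <- c(msg, "step must be positive")
  if (length(msg)) msg else TRUE
})

#' ScreeningResult: discriminative-coupling selection outcome
#'
#' Holds the per-pair (or per-pair-per-latency) Wilcoxon scores, the
#' permutation-derived threshold, the binary and median-sieved masks, the
#' temporal-consistency profile, and the selected pair indices.
#'
#' @slot scores numeric matrix (N_pairs x N_tau) or column matrix for the
#'   static case.
#' @slot threshold the permutation threshold (99.9th percentile of the pooled
#'   null score distribution), or \code{NA} for static top-k selection.
#' @slot mask binary supra-threshold indicator matrix I(r, tau).
#' @slot sieved mask after row-wise running-median sieving.
#' @slot profile per-pair persistence profile (row sums of the sieved mask;
#'   bootstrap-averaged profile when produced by [bootstrapSelect()]).
#' @slot selected integer vector of selected pair indices (positions in
#'   vec(W) ordering).
#' @slot nRand number of label permutations used for the threshold.
#' @slot nBoot number of bootstrap resamples (0 when not bootstrapped).
#'
#' @seealso [selectStaticFeatures()], [consistencyProfile()],
#'   [bootstrapSelect()]
#' @export
setClass("ScreeningResult",
  representation(scores = "matrix", threshold = "numeric", mask = "matrix",
                 sieved = "matrix", profile = "numeric", selected = "integer",
                 nRand = "integer", nBoot = "integer"))

setValidity("ScreeningResult", function(object) {
  msg <- character()
  if (length(object@profile) && nrow(object@scores) &&
      length(object@profile) != nrow(object@scores))
    msg <- c(msg, "profile must have one entry per pair")
  if (length(object@selected) &&
      any(object@selected < 1 | object@selected > nrow(object@scores)))
    msg <- c(msg, "selected indices out of range")
  if (length(msg)) msg else TRUE
})

#' ConfidenceClassifier: a calibrated linear MI-direction decoder
#'
#' A maximum-margin linear separator over selected-coupling space whose
#' output is a signed confidence in [-1, 1]: sign encodes the predicted
#' class (+ right / - left), magnitude the confidence (2 p(right) - 1 from
#' sigmoid probability calibration).
#'
#' @slot fit the underlying support-vector machine fit.
#' @slot center,scaleSd per-feature standardization learned on the training
#'   fold.
#' @slot features integer indices (into vec(W)) of the input couplings.
#' @slot platt intercept and slope of the sigmoid calibration, fitted on
#'   held-out (leave-one-out) decision values of the training set with
#'   regularized Platt targets, so confidences stay honest away from the
#'   training manifold.
#'
#' @seealso [fitConfidenceClassifier()], [predictConfidence()]
#' @export
setClass("ConfidenceClassifier",
  representation(fit = "ANY", center = "numeric", scaleSd = "numeric",
                 features = "integer", platt = "numeric"))

#' EnsembleModel: a time-lagged bank of latency-specific SVMs
#'
#' Member classifiers trained at selected latencies of the accuracy curve,
#' all sharing one fixed coupling set. The ensemble readout averages the
#' members' signed confidences after imposing their relative lags.
#'
#' @slot members list of \linkS4class{ConfidenceClassifier}.
#' @slot lags integer window indices tau_sel (strictly increasing).
#' @slot features shared selected-coupling index set.
#' @slot step window step (seconds) of the sequences the members expect.
#' @slot window window width (seconds).
#' @slot accuracy LOOCV accuracy of each member at its own latency.
#'
#' @seealso [buildEnsemble()], [ensembleReadout()]
#' @export
setClass("EnsembleModel",
  representation(members = "list", lags = "integer", features = "integer",
                 step = "numeric", window = "numeric", accuracy = "numeric"))

setValidity("EnsembleModel", function(object) {
  msg <- character()
  if (length(object@members) != length(object@lags))
    msg <- c(msg, "one lag per member required")
  if (length(object@lags) > 1 && any(diff(object@lags) <= 0))
    msg <- c(msg, "lags must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' SwitchModel: radial-basis event detector over readout segments
#'
#' Binary classifier (RBF kernel) that labels fixed-width segments of the
#' streaming ensemble readout as "MI event" versus "baseline", enabling
#' trigger-free (self-paced) operation.
#'
#' @slot fit the underlying RBF support-vector machine.
#' @slot width segment width in seconds (default 0.5).
#' @slot step readout step in seconds the segments are sampled at.
#' @slot threshold detection confidence threshold in (0, 1).
#' @slot segmentCounts named integer vector: how many \code{mi} and
#'   \code{baseline} segments the switch was trained on.
#'
#' @seealso [trainSwitch()], [streamDecode()]
#' @export
setClass("SwitchModel",
  representation(fit = "ANY", width = "numeric", step = "numeric",
                 threshold = "numeric", segmentCounts = "integer"))

setValidity("SwitchModel", function(object) {
  msg <- character()
  if (object@width <= 0) msg <- c(msg, "segment width must be positive")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})
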