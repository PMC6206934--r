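#' @include decoding.R
NULL

#' Build a time-lagged SVM ensemble from the accuracy curve
#'
#' Selects ensemble members among the latency-specific classifiers: local
#' maxima of the LOOCV accuracy curve above the floor qualify, are visited
#' in decreasing accuracy order, and are kept greedily subject to (a) a
#' pairwise lag separation of at least \code{minSeparation} seconds (so
#' members do not "collide": their integration windows are distinct) and
#' (b) a hyperplane dissimilarity check — a candidate whose hyperplane
#' normal has cosine similarity >= \code{maxSimilarity} with an already
#' kept member duplicates it and is dropped.
#'
#' @param curve LOOCV accuracy per latency, from [timeResolvedSvms()].
#' @param bank list of per-latency \linkS4class{ConfidenceClassifier}.
#' @param step window step of the underlying sequences (seconds).
#' @param window window width (seconds); the default lag separation.
#' @param minAccuracyFrac floor as a fraction of the curve maximum
#'   (default 0.9: only easy-detectable peaks qualify).
#' @param minSeparation minimum lag separation in seconds (default
#'   \code{window}).
#' @param maxSimilarity cosine-similarity cutoff between member hyperplane
#'   normals (default 0.95).
#' @param maxMembers optional cap on M.
#' @param maxLagSeconds restrict candidate members to lags within this many
#'   seconds of the onset-aligned latency grid (default \code{Inf}). A
#'   bounded lag span keeps the streaming readout trace long (it is
#'   truncated by the largest lag) and favours early, speedy-response
#'   members.
#' @return an \linkS4class{EnsembleModel} with strictly increasing lags.
#' @export
buildEnsemble <- function(curve, bank, step, window,
                          minAccuracyFrac = 0.9, minSeparation = window,
                          maxSimilarity = 0.95, maxMembers = Inf,
                          maxLagSeconds = Inf) {
  stopifnot(length(curve) == length(bank))
  maxLag <- min(length(curve), ceiling(maxLagSeconds / step) + 1L)
  floorAcc <- minAccuracyFrac * max(curve[seq_len(maxLag)])
  cand <- localMaxima(curve[seq_len(maxLag)])
  cand <- cand[curve[cand] >= floorAcc]
  if (!length(cand)) stop("no qualifying accuracy peak above the floor")
  cand <- cand[order(-curve[cand], cand)]
  sepTau <- max(1L, ceiling(minSeparation / step))
  kept <- integer(0)
  normals <- list()
  for (tau in cand) {
    if (length(kept) >= maxMembers) break
    if (length(kept) && any(abs(kept - tau) < sepTau)) next
    w <- hyperplaneNormal(bank[[tau]])
    dup <- any(vapply(normals, function(v)
      abs(cosineSimilarity(v, w)) >= maxSimilarity, logical(1)))
    if (dup) next
    kept <- c(kept, tau)
    normals <- c(normals, list(w))
  }
  o <- order(kept)
  kept <- kept[o]
  new("EnsembleModel", members = bank[kept], lags = as.integer(kept),
      features = bank[[kept[1]]]@features, step = step, window = window,
      accuracy = curve[kept])
}

#' Streaming ensemble readout
#'
#' Evaluates every ensemble member at every latency of a streaming
#' connectivity sequence (the members run in parallel on the same stream)
#' and combines them into the instantaneous classification index: for each
#' candidate onset position t, the mean of the member confidences read at
#' their own lags, z_ensemble(t) = (1/M) sum_i z^i(t + tau_sel_i). The
#' trace is truncated where a member's lag would run past the stream end.
#'
#' @param sequence a \linkS4class{ConnectivitySequence} (full vec(W[tau])
#'   stream; member features are extracted internally) computed at the
#'   ensemble's step.
#' @param ensemble an \linkS4class{EnsembleModel}.
#' @return list of class \code{ensembleReadout}: \code{Z} (M x N_tau member
#'   confidences), \code{z} (the classification-index trace),
#'   \code{onsetTimes} (hypothesized onset time of each trace sample,
#'   seconds relative to the epoch's event onset), \code{step} and
#'   \code{t0}.
#' @export
ensembleReadout <- function(sequence, ensemble) {
  stopifnot(is(sequence, "ConnectivitySequence"),
            is(ensemble, "EnsembleModel"))
  if (abs(sequence@step - ensemble@step) > 1e-9)
    stop("stream step does not match the ensemble's step")
  V <- vecW(sequence)
  nt <- ncol(V)
  M <- length(ensemble@members)
  feats <- ensemble@features
  Z <- matrix(0, M, nt)
  for (i in seq_len(M))
    Z[i, ] <- predictConfidence(ensemble@members[[i]],
                                t(V[feats, , drop = FALSE]))
  maxLag <- max(ensemble@lags)
  nOut <- nt - maxLag
  if (nOut < 1L) {
    warning("stream shorter than the ensemble's maximum lag; empty trace")
    z <- numeric(0)
    onsetTimes <- numeric(0)
  } else {
    z <- vapply(seq_len(nOut) - 1L, function(t0i)
      mean(Z[cbind(seq_len(M), t0i + ensemble@lags)]), numeric(1))
    onsetTimes <- (seq_len(nOut) - 1L) * sequence@step +
      sequence@times[1] + sequence@t0
  }
  structure(list(Z = Z, z = z, onsetTimes = onsetTimes,
                 step = sequence@step, t0 = sequence@t0),
            class = "ensembleReadout")
}
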