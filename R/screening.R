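#' @include utils.R connectivity.R
NULL

# Column-wise two-sample rank-sum |z| for a samples x features matrix whose
# first nA rows are group A. Vectorized: one order() call ranks all columns;
# columns containing ties are re-ranked exactly (midranks + tie-corrected
# variance). Returns 0 for all-tied (zero-variance) columns.
rankSumZ <- function(X, nA) {
  n <- nrow(X)
  p <- ncol(X)
  nB <- n - nA
  stopifnot(nA >= 1, nB >= 1)
  if (p == 0) return(numeric(0))
  g <- rep.int(seq_len(p), rep.int(n, p))
  xv <- as.vector(X)
  o <- order(g, xv)
  rk <- numeric(n * p)
  rk[o] <- rep.int(seq_len(n), p)
  xs <- xv[o]
  gs <- g[o]
  tiePos <- which(xs[-1] == xs[-length(xs)] & gs[-1] == gs[-length(gs)])
  varW <- rep(nA * nB * (n + 1) / 12, p)
  if (length(tiePos)) {
    tieCols <- unique(gs[tiePos])
    for (cc in tieCols) {
      col <- X[, cc]
      rk[((cc - 1) * n + 1):(cc * n)] <- rank(col)
      tl <- table(col)
      tl <- tl[tl > 1]
      varW[cc] <- nA * nB / 12 *
        ((n + 1) - sum(tl^3 - tl) / (n * (n - 1)))
    }
  }
  dim(rk) <- c(n, p)
  W <- colSums(rk[seq_len(nA), , drop = FALSE])
  z <- (W - nA * (n + 1) / 2) / sqrt(varW)
  z[varW <= 0] <- 0
  abs(z)
}

#' Wilcoxon discriminability scores
#'
#' Per-feature absolute standardized two-sample rank-sum statistic |z|
#' between two groups of patterns; higher means more class-discriminative.
#' Rank-based, hence invariant under monotone transforms of a feature;
#' all-tied features score 0.
#'
#' @param groupA,groupB numeric matrices, patterns (rows) x features
#'   (columns), with a common feature count.
#' @return numeric vector of |z| scores, one per feature.
#' @examples
#' wilcoxonScores(matrix(1:3), matrix(4:6))  # 4.5 / sqrt(5.25) = 1.964
#' @export
wilcoxonScores <- function(groupA, groupB) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (ncol(groupA) != ncol(groupB))
    stop("groups must share the feature dimension")
  if (nrow(groupA) < 2 || nrow(groupB) < 2)
    stop("at least 2 patterns per group required")
  rankSumZ(rbind(groupA, groupB), nrow(groupA))
}

#' Static top-k coupling selection
#'
#' Ranks couplings by their Wilcoxon score on static patterns and keeps the
#' k most discriminative ones (ties broken by ascending pair index, so the
#' selection is stable).
#'
#' @param left,right trials x N_pairs matrices of static vec(W) patterns.
#' @param k number of couplings to keep (default 10).
#' @return integer vector of k selected pair indices, in decreasing score
#'   order.
#' @export
selectStaticFeatures <- function(left, right, k = 10) {
  scores <- wilcoxonScores(left, right)
  if (k > length(scores))
    stop(sprintf("k = %d exceeds the %d available couplings", k,
                 length(scores)))
  order(-scores, seq_along(scores))[seq_len(k)]
}

# Stack a list of ConnectivitySequence (or plain matrices) into a
# trials x pairs x N_tau array, checking shape agreement.
sequenceArray <- function(seqs) {
  mats <- lapply(seqs, function(s) if (is(s, "ConnectivitySequence"))
    vecW(s) else as.matrix(s))
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("sequences disagree in N_pairs or N_tau")
  arr <- array(0, dim = c(length(mats), dims[1, 1], dims[2, 1]))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

#' Latency-resolved Wilcoxon scores
#'
#' Applies [wilcoxonScores()] at every latency of the stepping window,
#' assembling the Score(r, tau) field over all couplings and window
#' positions.
#'
#' @param left,right lists of \linkS4class{ConnectivitySequence} (or
#'   N_pairs x N_tau matrices), one per trial, sharing N_pairs and N_tau.
#' @return numeric matrix, N_pairs x N_tau.
#' @export
timeIndexedScores <- function(left, right) {
  al <- sequenceArray(left)
  ar <- sequenceArray(right)
  if (!all(dim(al)[2:3] == dim(ar)[2:3]))
    stop("left and right sequences disagree in N_pairs or N_tau")
  np <- dim(al)[2]; nt <- dim(al)[3]
  X <- rbind(matrix(al, nrow = dim(al)[1]), matrix(ar, nrow = dim(ar)[1]))
  matrix(rankSumZ(X, dim(al)[1]), np, nt)
}

#' Permutation threshold for time-indexed scores
#'
#' Builds the null score distribution by repeatedly shuffling the class
#' labels of the pooled left/right sequences, recomputing the latency-
#' resolved Wilcoxon scores, and pooling all features, latencies and
#' permutations; the 99.9th percentile of that pooled distribution is the
#' threshold above which a coupling is called significant (p < 0.001).
#'
#' @param left,right lists of sequences as in [timeIndexedScores()].
#' @param nRand number of label permutations (default 100).
#' @param percentile quantile of the pooled null distribution (default
#'   0.999).
#' @param seed seed for the permutation stream.
#' @return the scalar threshold, with the pooled null sample size as
#'   attribute \code{nullSize}.
#' @export
permutationThreshold <- function(left, right, nRand = 100,
                                 percentile = 0.999, seed = 1) {
  if (nRand < 20) stop("nRand must be at least 20")
  al <- sequenceArray(left)
  ar <- sequenceArray(right)
  nl <- dim(al)[1]; nr <- dim(ar)[1]
  if (nl + nr < 4) stop("too few trials to permute")
  X <- rbind(matrix(al, nrow = nl), matrix(ar, nrow = nr))
  n <- nl + nr
  set.seed(seed)
  pooled <- vector("list", nRand)
  for (b in seq_len(nRand)) {
    perm <- sample.int(n)
    pooled[[b]] <- rankSumZ(X[perm, , drop = FALSE], nl)
  }
  null <- unlist(pooled)
  thr <- as.numeric(quantile(null, percentile))
  attr(thr, "nullSize") <- length(null)
  thr
}

#' Temporal-consistency profile and coupling selection
#'
#' Thresholds the latency-resolved score field (Heaviside step at the
#' permutation threshold), removes supra-threshold runs shorter than the
#' persistence floor with a row-wise running median, and sums the sieved
#' mask along latency into a per-pair profile. Pairs with a non-zero
#' profile are the temporally consistent discriminative couplings.
#'
#' @param scores N_pairs x N_tau score matrix from [timeIndexedScores()].
#' @param threshold permutation threshold from [permutationThreshold()].
#' @param medianWindow odd running-median length; by default the smallest
#'   odd length whose half-width spans at least 100 ms at \code{step}.
#' @param step window step in seconds (used only for the default
#'   \code{medianWindow}).
#' @return a \linkS4class{ScreeningResult}.
#' @export
consistencyProfile <- function(scores, threshold, medianWindow = NULL,
                               step = 0.02) {
  if (is.null(medianWindow)) medianWindow <- oddMedianWindow(step)
  if (medianWindow %% 2 == 0) stop("medianWindow must be odd")
  mask <- (scores > threshold) * 1
  sieved <- runningMedianRows(mask, medianWindow)
  profile <- rowSums(sieved)
  new("ScreeningResult", scores = scores, threshold = as.numeric(threshold),
      mask = mask, sieved = sieved, profile = profile,
      selected = which(profile > 0), nRand = 0L, nBoot = 0L)
}

#' Bootstrap-aggregated coupling selection
#'
#' The selection used by all time-indexed decoders: trials are resampled
#' with replacement (within class) \code{nBoot} times; each resample's
#' latency-resolved scores are thresholded and sieved into a consistency
#' profile; the profiles are averaged; pairs whose average profile exceeds
#' the selection floor form the fixed feature set. If nothing survives, the
#' selection falls back (with a warning) to the top-k static ranking of the
#' time-averaged patterns.
#'
#' @param left,right lists of sequences as in [timeIndexedScores()].
#' @param nBoot bootstrap resamples (default 30).
#' @param nRand label permutations for the threshold (default 100).
#' @param medianWindow,step consistency-sieve parameters, as in
#'   [consistencyProfile()].
#' @param floor selection floor on the average profile. The default asks a
#'   "stable" coupling to persist, in the bootstrap-averaged sense, for at
#'   least a tenth of the trial's latencies (\code{0.1 * N_tau}, and never
#'   less than half a minimal sieve-surviving run). The profile is a
#'   latency count, so a constant in (0, 1) would admit any pair that
#'   survives occasionally, and marginal couplings that flicker above the
#'   threshold would bias the downstream readout.
#' @param fallbackK static top-k size used when the selection is empty.
#' @param seed seed controlling both the permutation and bootstrap streams.
#' @param threshold optionally, a precomputed permutation threshold.
#' @return a \linkS4class{ScreeningResult} whose \code{profile} is the
#'   bootstrap-averaged profile.
#' @export
bootstrapSelect <- function(left, right, nBoot = 30, nRand = 100,
                            medianWindow = NULL, step = 0.02, floor = NULL,
                            fallbackK = 10, seed = 1, threshold = NULL) {
  if (nBoot < 2) stop("nBoot must be at least 2")
  if (is.null(medianWindow)) medianWindow <- oddMedianWindow(step)
  al <- sequenceArray(left)
  ar <- sequenceArray(right)
  nl <- dim(al)[1]; nr <- dim(ar)[1]
  np <- dim(al)[2]; nt <- dim(al)[3]
  if (is.null(floor))
    floor <- max(0.5 * (medianWindow + 1) / 2, 0.1 * nt)
  if (is.null(threshold))
    threshold <- permutationThreshold(left, right, nRand = nRand,
                                      seed = seed)
  Xl <- matrix(al, nrow = nl); Xr <- matrix(ar, nrow = nr)
  set.seed(seed + 1L)
  profSum <- numeric(np)
  for (b in seq_len(nBoot)) {
    bi <- sample.int(nl, nl, replace = TRUE)
    bj <- sample.int(nr, nr, replace = TRUE)
    sc <- matrix(rankSumZ(rbind(Xl[bi, , drop = FALSE],
                                Xr[bj, , drop = FALSE]), nl), np, nt)
    res <- consistencyProfile(sc, threshold, medianWindow)
    profSum <- profSum + pairProfile(res)
  }
  avgProfile <- profSum / nBoot
  selected <- which(avgProfile > floor)
  fullScores <- timeIndexedScores(left, right)
  if (!length(selected)) {
    warning("empty bootstrap selection; falling back to static top-",
            fallbackK, " ranking")
    staticL <- t(apply(al, 1, function(m) rowMeans(matrix(m, np, nt))))
    staticR <- t(apply(ar, 1, function(m) rowMeans(matrix(m, np, nt))))
    selected <- selectStaticFeatures(staticL, staticR,
                                     k = min(fallbackK, np))
  }
  mask <- (fullScores > threshold) * 1
  new("ScreeningResult", scores = fullScores,
      threshold = as.numeric(threshold), mask = mask,
      sieved = runningMedianRows(mask, medianWindow),
      profile = avgProfile, selected = as.integer(selected),
      nRand = as.integer(nRand), nBoot = as.integer(nBoot))
}
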