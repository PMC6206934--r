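#' @importFrom stats runmed rnorm runif quantile median fft sd var mad predict
NULL

# Derive per-unit sub-seeds from one master seed so that e.g. each simulated
# trial has its own reproducible stream. Kept below 2^31 - 1.
subSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Row-wise running median of a binary mask, zero-padded at both ends so that
# supra-threshold runs shorter than the persistence floor are eliminated
# (a run must outlast (k+1)/2 window positions to survive).
runningMedianRows <- function(mask, k) {
  stopifnot(k %% 2 == 1)
  if (k == 1 || ncol(mask) == 0) return(mask)
  h <- (k - 1) / 2
  pad <- matrix(0, nrow(mask), h)
  padded <- cbind(pad, mask, pad)
  out <- t(apply(padded, 1, function(row) runmed(row, k, endrule = "keep")))
  out[, (h + 1):(h + ncol(mask)), drop = FALSE]
}

# Smallest odd median-filter length whose half-width spans at least
# `persist` seconds at the given window step (temporal-consistency floor).
oddMedianWindow <- function(step, persist = 0.1) {
  k <- 2 * ceiling(persist / step) + 1
  max(3L, as.integer(k))
}

# Indices of strict-or-plateau local maxima of a numeric curve
# (endpoints qualify when they dominate their single neighbour).
localMaxima <- function(x) {
  n <- length(x)
  if (n == 1L) return(1L)
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  which(x >= left & x > right | x > left & x >= right)
}

# Cosine similarity of two vectors (0 for degenerate input).
cosineSimilarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
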