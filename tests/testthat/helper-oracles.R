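# Independent oracles used across test files.

# Naive per-pair PLV: scalar loop over pairs and samples.
plvLoop <- function(trial, from, to) {
  phase <- t(apply(trial, 1, function(ch) {
    n <- length(ch)
    X <- fft(ch)
    h <- numeric(n)
    if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
    else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
    Arg(fft(X * h, inverse = TRUE) / n)
  }))
  nch <- nrow(trial)
  W <- diag(1, nch)
  for (k in seq_len(nch - 1)) {
    for (r in (k + 1):nch) {
      d <- phase[k, from:to] - phase[r, from:to]
      W[k, r] <- W[r, k] <- Mod(mean(exp(1i * d)))
    }
  }
  W
}

# Floyd–Warshall all-pairs shortest paths on distance matrix d.
floydWarshall <- function(d) {
  n <- nrow(d)
  l <- d
  for (mid in seq_len(n))
    for (a in seq_len(n))
      for (b in seq_len(n))
        if (l[a, mid] + l[mid, b] < l[a, b])
          l[a, b] <- l[a, mid] + l[mid, b]
  l
}

# Global efficiency from a weight matrix via Floyd–Warshall.
geBrute <- function(W, eps = 1e-6) {
  d <- 1 - pmin(W, 1 - eps)
  diag(d) <- 0
  d[W <= 0] <- Inf
  diag(d) <- 0
  l <- floydWarshall(d)
  n <- nrow(W)
  inv <- 1 / l
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Exact permutation-distribution z of the rank-sum statistic: enumerate all
# group-A assignments, compute mean/var of the rank-sum, standardize.
rankSumZExact <- function(a, b) {
  x <- c(a, b)
  nA <- length(a)
  rk <- rank(x)
  combs <- utils::combn(length(x), nA)
  Ws <- apply(combs, 2, function(idx) sum(rk[idx]))
  W <- sum(rk[seq_len(nA)])
  s <- sd(Ws) * sqrt((length(Ws) - 1) / length(Ws))  # population sd
  if (s == 0) return(0)
  abs((W - mean(Ws)) / s)
}
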