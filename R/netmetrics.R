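#' @include connectivity.R
NULL

asAdjacency <- function(W) {
  if (is(W, "ConnectivityPattern")) W <- plvAdjacency(W)
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  W
}

# PLV weights -> distances d = 1 - w with weights capped at 1 - eps so a
# perfect coupling cannot yield a zero distance (and an unbounded 1/l).
plvDistances <- function(W, eps = 1e-6) {
  W <- pmin(W, 1 - eps)
  d <- 1 - W
  diag(d) <- 0
  d
}

# All-pairs shortest path lengths over d = 1 - w (Dijkstra, via igraph).
shortestPathLengths <- function(W, eps = 1e-6) {
  d <- plvDistances(asAdjacency(W), eps)
  n <- nrow(d)
  mask <- d < 1          # w > 0: an edge exists (PLV graphs are dense)
  diag(mask) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(mask, mode = "undirected",
                                           diag = FALSE)
  wts <- d[igraph::as_edgelist(g, names = FALSE)]
  igraph::distances(g, weights = wts, algorithm = "dijkstra")
}

#' Node strength of a PLV graph
#'
#' Sum of the connectivity weights attached to each node (off-diagonal row
#' sums) — an approximate centrality of each recording site.
#'
#' @param W a \linkS4class{ConnectivityPattern} or symmetric weight matrix.
#' @return numeric vector S_k, one entry per node.
#' @examples
#' W <- matrix(c(1, .5, .2, .5, 1, .4, .2, .4, 1), 3)
#' nodeStrength(W)  # 0.7 0.9 0.6
#' @export
nodeStrength <- function(W) {
  W <- asAdjacency(W)
  rowSums(W) - diag(W)
}

#' Global efficiency of a weighted PLV graph
#'
#' Average inverse shortest-path length over ordered node pairs, with path
#' lengths computed by Dijkstra's algorithm on the distances d = 1 - w.
#' A disconnected pair contributes 0 (its inverse path length).
#'
#' @param W a \linkS4class{ConnectivityPattern} or symmetric weight matrix.
#' @param eps weights are capped at 1 - eps before the distance transform.
#' @return scalar GE.
#' @examples
#' globalEfficiency(matrix(.5, 3, 3) + diag(.5, 3))  # all l = 0.5 -> 2
#' @export
globalEfficiency <- function(W, eps = 1e-6) {
  l <- shortestPathLengths(W, eps)
  n <- nrow(l)
  if (n < 2) return(0)
  inv <- 1 / l
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency of a weighted PLV graph
#'
#' For each node k, the efficiency of the subgraph G_k induced by k's
#' neighbours (w > 0), using only intra-subgraph edges and distances from
#' the full graph restricted to G_k (the Latora-Marchiori formulation);
#' the result is the mean of LE(k) over nodes. Nodes with fewer than two
#' neighbours contribute 0.
#'
#' @param W a \linkS4class{ConnectivityPattern} or symmetric weight matrix.
#' @param eps weight cap as in [globalEfficiency()].
#' @return scalar LE.
#' @export
localEfficiency <- function(W, eps = 1e-6) {
  W <- asAdjacency(W)
  n <- nrow(W)
  offdiag <- W - diag(diag(W))
  le <- vapply(seq_len(n), function(k) {
    nb <- which(offdiag[k, ] > 0)
    if (length(nb) < 2) return(0)
    globalEfficiency(W[nb, nb, drop = FALSE], eps)
  }, numeric(1))
  mean(le)
}

#' Network-metric triad of connectivity patterns
#'
#' Computes mean strength, global efficiency and local efficiency for one or
#' several connectivity patterns and returns them as a table suitable for
#' delimited-text export (one row per trial/pattern).
#'
#' @param patterns a \linkS4class{ConnectivityPattern}, a weight matrix, or
#'   a list of either.
#' @param subject,band,condition optional metadata columns.
#' @return data.frame with columns \code{subject}, \code{band},
#'   \code{condition}, \code{trial}, \code{meanStrength}, \code{GE},
#'   \code{LE}.
#' @export
networkMetrics <- function(patterns, subject = NA_character_,
                           band = NA_character_,
                           condition = NA_character_) {
  if (!is.list(patterns)) patterns <- list(patterns)
  rows <- lapply(seq_along(patterns), function(i) {
    W <- asAdjacency(patterns[[i]])
    data.frame(subject = subject, band = band, condition = condition,
               trial = i, meanStrength = mean(nodeStrength(W)),
               GE = globalEfficiency(W), LE = localEfficiency(W),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
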