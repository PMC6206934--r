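#' @importFrom stats wilcox.test p.adjust
NULL

#' Common good-sensor set across subjects
#'
#' Intersection of per-subject good-channel lists, returned in the order of
#' the first subject's montage (order-stable), so that group-level
#' connectivity patterns can be confined to sensors available in everyone.
#'
#' @param channelLists list of character vectors, one per subject.
#' @return character vector of channels present in all subjects.
#' @export
commonGoodSensors <- function(channelLists) {
  stopifnot(length(channelLists) >= 1)
  common <- Reduce(intersect, channelLists)
  if (!length(common)) stop("no sensor is good in all subjects")
  channelLists[[1]][channelLists[[1]] %in% common]
}

#' Two-group rank-sum test utility
#'
#' Generic two-sample Wilcoxon rank-sum comparison of per-subject summary
#' values (e.g. best accuracies per cohort), with a one-tailed option.
#'
#' @param groupA,groupB numeric vectors.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"} (A versus B).
#' @return the p-value.
#' @export
rankSumCompare <- function(groupA, groupB, alternative = "two.sided") {
  wilcox.test(groupA, groupB, alternative = alternative,
              exact = NULL)$p.value
}

#' Cohort contrast of pairwise couplings
#'
#' Compares every coupling between two cohorts of subject-averaged
#' connectivity patterns with the Wilcoxon rank-sum test, corrects the
#' p-values for multiple testing with the Benjamini-Hochberg false
#' discovery rate at level \code{alpha}, and attaches the median-difference
#' map med(A) - med(B) whose sign encodes the direction of the effect.
#' Patterns must already be confined to the common good-sensor set.
#'
#' @param groupA,groupB subjects x N_pairs matrices of subject-averaged
#'   vec(W) patterns.
#' @param alpha FDR level (default 0.05).
#' @return list of class \code{groupContrast}: \code{p} (raw),
#'   \code{pAdjusted}, \code{significant} (logical mask), \code{medianDiff},
#'   \code{alpha}, \code{method}.
#' @export
compareCouplings <- function(groupA, groupB, alpha = 0.05) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (ncol(groupA) != ncol(groupB))
    stop("cohorts must share the coupling dimension")
  if (nrow(groupA) < 2 || nrow(groupB) < 2)
    stop("at least 2 subjects per group required")
  # small cohorts with tied values fall back to the normal approximation
  p <- vapply(seq_len(ncol(groupA)), function(r)
    suppressWarnings(wilcox.test(groupA[, r], groupB[, r],
                                 exact = NULL)$p.value),
    numeric(1))
  pAdj <- p.adjust(p, method = "BH")
  medDiff <- apply(groupA, 2, median) - apply(groupB, 2, median)
  structure(list(p = p, pAdjusted = pAdj, significant = pAdj < alpha,
                 medianDiff = medDiff, alpha = alpha, method = "BH"),
            class = "groupContrast")
}

#' Cohort contrast of network metrics
#'
#' Wilcoxon rank-sum comparison of per-subject network-metric summaries
#' (trial-averaged strength, global and local efficiency) between two
#' cohorts, per metric x band x condition cell, Bonferroni-corrected
#' across the whole tested family.
#'
#' @param groupA,groupB data.frames with columns \code{subject},
#'   \code{band}, \code{condition}, \code{metric}, \code{value} (one row
#'   per subject x band x condition x metric, values already averaged
#'   across trials).
#' @param alpha significance level applied to the corrected p-values
#'   (default 0.01).
#' @return data.frame with one row per tested cell: \code{metric},
#'   \code{band}, \code{condition}, \code{p}, \code{pAdjusted},
#'   \code{significant}, \code{medianDiff}.
#' @export
compareNetworkMetrics <- function(groupA, groupB, alpha = 0.01) {
  need <- c("subject", "band", "condition", "metric", "value")
  stopifnot(all(need %in% names(groupA)), all(need %in% names(groupB)))
  keyOf <- function(d) sort(unique(paste(d$metric, d$band, d$condition,
                                         sep = "\r")))
  if (!identical(keyOf(groupA), keyOf(groupB)))
    stop("cohorts test different metric/band/condition families")
  cells <- unique(groupA[, c("metric", "band", "condition")])
  cells <- cells[do.call(order, cells), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- function(d) d$value[d$metric == cells$metric[i] &
                                 d$band == cells$band[i] &
                                 d$condition == cells$condition[i]]
    a <- sel(groupA); b <- sel(groupB)
    data.frame(metric = cells$metric[i], band = cells$band[i],
               condition = cells$condition[i],
               p = suppressWarnings(wilcox.test(a, b,
                                                exact = NULL)$p.value),
               medianDiff = median(a) - median(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pAdjusted <- p.adjust(out$p, method = "bonferroni")
  out$significant <- out$pAdjusted < alpha
  out[, c("metric", "band", "condition", "p", "pAdjusted", "significant",
          "medianDiff")]
}
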