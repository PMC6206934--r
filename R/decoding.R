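#' @include screening.R
#' @importFrom stats glm plogis quasibinomial coef
NULL

classLevels <- c("left", "right")

standardize <- function(X, center = NULL, scaleSd = NULL) {
  if (is.null(center)) {
    center <- colMeans(X)
    scaleSd <- apply(X, 2, sd)
    scaleSd[scaleSd == 0] <- 1
  }
  list(X = sweep(sweep(X, 2, center), 2, scaleSd, "/"),
       center = center, scaleSd = scaleSd)
}

normalizeLabels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.numeric(y)) y <- ifelse(y > 0, "right", "left")
  bad <- setdiff(unique(y), classLevels)
  if (length(bad)) stop("labels must be left/right (or ±1)")
  y
}

linearSvm <- function(X, y, cost) {
  e1071::svm(X, factor(y, levels = classLevels), kernel = "linear",
             cost = cost, scale = FALSE)
}

# Decision value oriented so that positive favours "right" (libsvm signs the
# value towards the first class of the pair label).
svmDecision <- function(fit, X) {
  pr <- predict(fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  flip <- colnames(dv)[1] == "left/right"
  as.numeric(if (flip) -dv[, 1] else dv[, 1])
}

# Platt's sigmoid with regularized targets: finite coefficients even when
# the decision values separate the classes perfectly.
plattFit <- function(dv, y) {
  pos <- y == "right"
  np <- sum(pos); nn <- sum(!pos)
  target <- ifelse(pos, (np + 1) / (np + 2), 1 / (nn + 2))
  fit <- suppressWarnings(glm(target ~ dv, family = quasibinomial()))
  cf <- coef(fit)
  if (any(!is.finite(cf))) cf <- c(0, 1)
  unname(cf)
}

#' Fit a calibrated linear MI-direction decoder
#'
#' Trains a maximum-margin linear separator (C = 1, features standardized on
#' the training set) on selected-coupling patterns and calibrates a signed
#' confidence in [-1, 1]: a sigmoid is fitted to held-out (leave-one-out)
#' decision values of the training set, and a pattern's confidence is
#' 2 p(right) - 1, so the sign encodes the predicted side and the magnitude
#' the (honestly calibrated) confidence.
#'
#' @param X numeric matrix, patterns (rows) x selected couplings (columns).
#' @param y class labels (\code{"left"}/\code{"right"}, or a factor/±1
#'   vector where +1 means right).
#' @param features optional integer identity of the columns (indices into
#'   vec(W)), carried for bookkeeping.
#' @param cost SVM regularization constant (default 1; no tuning).
#' @return a \linkS4class{ConfidenceClassifier}.
#' @export
fitConfidenceClassifier <- function(X, y, features = seq_len(ncol(X)),
                                    cost = 1) {
  X <- as.matrix(X)
  y <- normalizeLabels(y)
  if (length(unique(y)) < 2)
    stop("both classes must be present in the training set")
  if (min(table(y)) < 2)
    stop("at least 2 samples per class required")
  st <- standardize(X)
  n <- nrow(X)
  dv <- numeric(n)
  for (i in seq_len(n)) {
    fit_i <- linearSvm(st$X[-i, , drop = FALSE], y[-i], cost)
    dv[i] <- svmDecision(fit_i, st$X[i, , drop = FALSE])
  }
  fit <- linearSvm(st$X, y, cost)
  new("ConfidenceClassifier", fit = fit, center = st$center,
      scaleSd = st$scaleSd, features = as.integer(features),
      platt = plattFit(dv, y))
}

#' @describeIn ConfidenceClassifier signed confidence 2 p(right) - 1 for new
#'   patterns.
#' @param newdata matrix (or vector) of patterns over the model's features.
#' @export
setMethod("predictConfidence", "ConfidenceClassifier",
  function(object, newdata) {
    if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
    Xs <- standardize(as.matrix(newdata), object@center, object@scaleSd)$X
    dv <- svmDecision(object@fit, Xs)
    p <- plogis(object@platt[1] + object@platt[2] * dv)
    2 * p - 1
  })

#' Hard class prediction of a confidence classifier
#'
#' @param object a \linkS4class{ConfidenceClassifier}.
#' @param newdata matrix of patterns.
#' @return character vector of \code{"left"}/\code{"right"}.
#' @export
predictClass <- function(object, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  Xs <- standardize(as.matrix(newdata), object@center, object@scaleSd)$X
  as.character(predict(object@fit, Xs))
}

# Hyperplane normal (in standardized feature space) of a linear SVM fit.
hyperplaneNormal <- function(clf) {
  as.numeric(crossprod(clf@fit$coefs, clf@fit$SV))
}

#' Static-scenario LOOCV accuracy
#'
#' Leave-one-out cross-validation of the static decoding scenario: in each
#' of the 2 N_trials folds the top-k coupling selection is re-run on the
#' remaining 2 N_trials - 1 training trials (selection embodied in the
#' validation loop, so the held-out trial never leaks into it), a linear
#' SVM is fitted, and the held-out trial is predicted. Accuracy is the
#' fraction of correct predictions over all folds.
#'
#' @param left,right trials x N_pairs static pattern matrices (or
#'   band-limited \linkS4class{TrialSet}s, in which case patterns are
#'   computed over the full epoch).
#' @param k couplings selected per fold (default 10).
#' @param cost SVM regularization constant.
#' @return list: \code{accuracy}, \code{nFolds}, \code{nTrain} (training
#'   trials per fold), \code{predictions}, \code{truth}, and
#'   \code{foldFeatures} (the per-fold selections, for leak auditing).
#' @export
loocvStaticAccuracy <- function(left, right, k = 10, cost = 1) {
  if (is(left, "TrialSet")) left <- staticPatterns(left)
  if (is(right, "TrialSet")) right <- staticPatterns(right)
  X <- rbind(left, right)
  y <- rep(classLevels, c(nrow(left), nrow(right)))
  n <- nrow(X)
  if (n < 4) stop("at least 4 trials required for LOOCV")
  preds <- character(n)
  foldFeatures <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    sel <- selectStaticFeatures(X[tr[y[tr] == "left"], , drop = FALSE],
                                X[tr[y[tr] == "right"], , drop = FALSE],
                                k = k)
    foldFeatures[[i]] <- sel
    st <- standardize(X[tr, sel, drop = FALSE])
    fit <- linearSvm(st$X, y[tr], cost)
    xs <- standardize(X[i, sel, drop = FALSE], st$center, st$scaleSd)$X
    preds[i] <- as.character(predict(fit, xs))
  }
  list(accuracy = mean(preds == y), nFolds = n, nTrain = n - 1L,
       predictions = preds, truth = y, foldFeatures = foldFeatures)
}

#' Latency-specific SVM bank with LOOCV accuracy curve
#'
#' For every latency tau of the time-indexed connectivity sequences, trains
#' an "instantaneous" linear SVM on the selected couplings at that latency
#' and estimates its LOOCV accuracy. The coupling set is fixed beforehand
#' (by [bootstrapSelect()]) and shared by all latencies; only the SVM fit
#' follows the LOOCV loop. Alongside the accuracy curve, a calibrated
#' \linkS4class{ConfidenceClassifier} is fitted on all trials at each
#' latency (its sigmoid calibrated on the fold-wise held-out decision
#' values) — the bank from which ensemble members are drawn.
#'
#' @param left,right lists of \linkS4class{ConnectivitySequence}, one per
#'   trial.
#' @param selected integer vector of selected pair indices (non-empty).
#' @param cost SVM regularization constant.
#' @return list: \code{accuracy} (length N_tau), \code{bank} (list of
#'   \linkS4class{ConfidenceClassifier}), \code{step}, \code{window},
#'   \code{times} and \code{selected}.
#' @export
timeResolvedSvms <- function(left, right, selected, cost = 1) {
  if (!length(selected)) stop("empty feature set")
  al <- sequenceArray(left)
  ar <- sequenceArray(right)
  nt <- dim(al)[3]
  nl <- dim(al)[1]; nr <- dim(ar)[1]
  y <- rep(classLevels, c(nl, nr))
  n <- nl + nr
  acc <- numeric(nt)
  bank <- vector("list", nt)
  for (tau in seq_len(nt)) {
    Xt <- rbind(matrix(al[, selected, tau], nrow = nl),
                matrix(ar[, selected, tau], nrow = nr))
    st <- standardize(Xt)
    preds <- character(n)
    dv <- numeric(n)
    for (i in seq_len(n)) {
      sti <- standardize(Xt[-i, , drop = FALSE])
      fit_i <- linearSvm(sti$X, y[-i], cost)
      xs <- standardize(Xt[i, , drop = FALSE], sti$center, sti$scaleSd)$X
      preds[i] <- as.character(predict(fit_i, xs))
      dv[i] <- svmDecision(fit_i, xs)
    }
    acc[tau] <- mean(preds == y)
    bank[[tau]] <- new("ConfidenceClassifier",
                       fit = linearSvm(st$X, y, cost),
                       center = st$center, scaleSd = st$scaleSd,
                       features = as.integer(selected),
                       platt = plattFit(dv, y))
  }
  s1 <- if (is(left[[1]], "ConnectivitySequence")) left[[1]] else NULL
  list(accuracy = acc, bank = bank,
       step = if (is.null(s1)) NA_real_ else s1@step,
       window = if (is.null(s1)) NA_real_ else s1@window,
       times = if (is.null(s1)) seq_len(nt) else s1@times,
       selected = as.integer(selected))
}
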