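#' Analytic signal of a real-valued series
#'
#' Builds the analytic signal x + i H(x) through the standard FFT
#' half-spectrum construction (zeroing negative frequencies and doubling the
#' positive ones).
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analyticSignal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of band-limited trials
#'
#' Per-channel instantaneous phase (radians, in (-pi, pi]) from the Hilbert
#' analytic signal. The input is expected to be narrowband (one of the seven
#' rhythms); for broadband input the phase is still defined but loses its
#' oscillatory interpretation. The phase is computed once over the full
#' epoch, so that downstream sliding windows can slice the phase series
#' without incurring per-window Hilbert edge effects.
#'
#' @param trial channels x samples numeric matrix (one epoch).
#' @return channels x samples matrix of phases in radians.
#' @examples
#' fs <- 256; t <- seq(0, 1 - 1 / fs, by = 1 / fs)
#' ph <- instantaneousPhase(rbind(cos(2 * pi * 10 * t), sin(2 * pi * 10 * t)))
#' @export
instantaneousPhase <- function(trial) {
  stopifnot(is.matrix(trial))
  flat <- apply(trial, 1, function(ch) all(ch == ch[1]))
  if (any(flat))
    warning("constant channel(s) have undefined phase: ",
            paste(which(flat), collapse = ", "))
  t(apply(trial, 1, function(ch) Arg(analyticSignal(ch))))
}
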