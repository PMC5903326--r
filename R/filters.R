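# Linear-phase FIR design and causal application.
#
# Filters are even-order (type I) symmetric FIRs designed by weighted least
# squares of the real amplitude response on a dense frequency grid, with
# don't-care transition regions. Symmetry is exact by construction, so the
# group delay is exactly order/2 samples at every frequency. Application is
# causal (zero initial state), matching an online system that filters 1-s
# windows as they elapse.

ls_fir <- function(order, low, high, fs, transition, stop_weight, type) {
  if (order %% 2 != 0) abort("filter order must be even (type-I linear phase)")
  nyq <- fs / 2
  if (low <= 0 || high <= low || high >= nyq) {
    abort("band edges must satisfy 0 < low < high < fs/2")
  }
  M <- order / 2
  grid <- seq(0, pi, length.out = 2048)
  f <- grid * fs / (2 * pi)
  lo_stop <- if (low - transition > 1) low - transition else low / 2
  hi_stop <- min(high + transition, (high + nyq) / 2)
  inband <- f >= low & f <= high
  outband <- f <= lo_stop | f >= hi_stop
  if (type == "pass") {
    pass <- inband
    stop <- outband
  } else {
    pass <- outband
    stop <- inband
  }
  keep <- pass | stop
  d <- as.numeric(pass[keep])
  w <- ifelse(stop[keep], stop_weight, 1)
  basis <- cos(outer(grid[keep], 0:M)) # A(w) = a0 + sum_k a_k cos(kw)
  sw <- sqrt(w)
  a <- solve(crossprod(basis * sw), crossprod(basis * sw, d * sw))
  a <- as.numeric(a)
  c(rev(a[-1]) / 2, a[1], a[-1] / 2)
}

#' Design a linear-phase FIR band-pass filter
#'
#' Even-order symmetric (type I) FIR with `order + 1` coefficients, designed
#' by weighted least squares with don't-care transition bands. Group delay is
#' exactly `order / 2` samples.
#'
#' @param low,high Passband edges in Hz, `0 < low < high < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Even filter order (default 30, i.e. 31 taps).
#' @param transition Transition bandwidth in Hz on each side of the passband.
#' @param stop_weight Relative least-squares weight of the stopbands.
#' @return Numeric coefficient vector of length `order + 1`.
#' @export
#' @examples
#' b <- design_fir_bandpass(8, 12, fs = 256)
#' length(b)
design_fir_bandpass <- function(low, high, fs, order = 30,
                                transition = 8, stop_weight = 2) {
  ls_fir(order, low, high, fs, transition, stop_weight, "pass")
}

#' Design a linear-phase FIR band-stop filter
#'
#' @inheritParams design_fir_bandpass
#' @param low,high Stopband edges in Hz.
#' @return Numeric coefficient vector of length `order + 1`.
#' @export
design_fir_bandstop <- function(low, high, fs, order = 30,
                                transition = 18, stop_weight = 2) {
  ls_fir(order, low, high, fs, transition, stop_weight, "stop")
}

#' Gain of an FIR filter at given frequencies
#'
#' @param coef FIR coefficient vector.
#' @param freq Frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @return Magnitude response at `freq`.
#' @export
fir_gain <- function(coef, freq, fs) {
  k <- seq_along(coef) - 1
  vapply(freq, function(f) Mod(sum(coef * exp(-1i * 2 * pi * f / fs * k))),
         numeric(1))
}

# Causal zero-state FIR filtering of every column of X (samples x signals),
# via FFT linear convolution truncated to the input length. Identical to
# direct convolution sum_k b[k] x[n-k] with x[<1] = 0.
fir_filter_mat <- function(coef, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  L <- length(coef)
  nfft <- next_pow2(n + L - 1)
  B <- fft(c(coef, rep(0, nfft - L)))
  Xp <- rbind(X, matrix(0, nfft - n, ncol(X)))
  Y <- Re(mvfft(mvfft(Xp) * B, inverse = TRUE)) / nfft
  Y[seq_len(n), , drop = FALSE]
}

#' Apply a causal FIR filter
#'
#' @param coef FIR coefficient vector.
#' @param x Numeric vector, or matrix with signals in columns.
#' @return Filtered signal(s), same shape as `x`; causal with zero initial
#'   state, so the output is delayed by `order / 2` samples.
#' @export
fir_filter <- function(coef, x) {
  if (is.matrix(x)) return(fir_filter_mat(coef, x))
  drop(fir_filter_mat(coef, matrix(x, ncol = 1)))
}
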