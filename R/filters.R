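# IIR filter design and application.
#
# The environment this package targets has no dedicated signal-processing
# package, so the small amount of classical DSP needed here (Butterworth
# band-pass via the bilinear transform, a biquad notch, zero-phase
# forward-backward filtering) is implemented directly. Designs follow the
# standard textbook construction and were validated against an independent
# reference implementation; see tests.

# Polynomial coefficients (descending powers) from roots.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, ri * p)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' Builds an analog Butterworth low-pass prototype of the given order,
#' transforms it to a band-pass, and discretizes by the bilinear transform
#' with frequency prewarping. The resulting filter has `2 * order` poles.
#'
#' @param order Prototype order (the band-pass has twice this many poles).
#' @param low_hz,high_hz Pass-band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs / 2`.
#' @param fs Sampling rate in Hz.
#' @return A list with numerator `b` and denominator `a` coefficients
#'   (denominator normalized so `a[1] == 1`).
#' @export
butter_bandpass <- function(order, low_hz, high_hz, fs) {
  if (!(is.numeric(order) && length(order) == 1L && order >= 1))
    stop("`order` must be a positive integer", call. = FALSE)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  fs2 <- 2 * fs
  # prewarped analog edge frequencies (rad/s)
  w1 <- fs2 * tan(pi * low_hz / fs)
  w2 <- fs2 * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order)) # LHP prototype poles
  # low-pass -> band-pass in the analog domain
  pl <- p * bw / 2
  pbp <- c(pl + sqrt(pl^2 - w0^2), pl - sqrt(pl^2 - w0^2))
  zbp <- rep(0 + 0i, order)
  kbp <- bw^order
  # bilinear transform
  pd <- (fs2 + pbp) / (fs2 - pbp)
  zd <- c((fs2 + zbp) / (fs2 - zbp), rep(-1 + 0i, length(pbp) - length(zbp)))
  kd <- kbp * Re(prod(fs2 - zbp) / prod(fs2 - pbp))
  b <- Re(kd * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b / a[1], a = a / a[1])
}

#' Design a second-order IIR notch filter
#'
#' Constant-gain biquad notch (unit gain away from the notch, zero at the
#' center frequency). Bandwidth is `center_hz / q_factor`.
#'
#' @param center_hz Notch center frequency in Hz (`< fs / 2`).
#' @param q_factor Quality factor; higher is narrower. Default 30.
#' @param fs Sampling rate in Hz.
#' @return A list with `b` and `a` coefficients.
#' @export
iir_notch <- function(center_hz, q_factor = 30, fs) {
  if (!(center_hz > 0 && center_hz < fs / 2))
    stop("`center_hz` must lie in (0, fs/2)", call. = FALSE)
  if (q_factor <= 0) stop("`q_factor` must be positive", call. = FALSE)
  w0 <- 2 * pi * center_hz / fs
  alpha <- sin(w0) / (2 * q_factor)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Complex frequency response of a digital filter
#'
#' Evaluates `H(e^{i 2 pi f / fs})` for the rational transfer function with
#' coefficients `b`, `a` (in z^-1 convention).
#'
#' @param b,a Filter coefficients.
#' @param f Frequencies in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return Complex vector of the same length as `f`.
#' @export
filter_response <- function(b, a, f, fs) {
  vapply(f, function(fi) {
    z <- exp(-1i * 2 * pi * fi / fs)
    num <- sum(b * z^(seq_along(b) - 1))
    den <- sum(a * z^(seq_along(a) - 1))
    num / den
  }, complex(1))
}

# Single forward pass of an IIR filter with zero initial state
# (direct-form II transposed, compiled).
lfilter <- function(x, b, a) {
  .Call(nq_lfilter, as.double(x), as.double(b / a[1]), as.double(a / a[1]))
}

# Number of samples for the impulse response to decay below `tol`,
# from the slowest pole of the denominator.
settle_samples <- function(a, tol = 1e-6) {
  if (length(a) <= 1L) return(1L)
  r <- Mod(polyroot(rev(a)))
  rmax <- max(r)
  if (rmax >= 1) stop("unstable filter: pole on or outside the unit circle",
                      call. = FALSE)
  if (rmax == 0) return(length(a))
  as.integer(ceiling(log(tol) / log(rmax)))
}

#' Apply a digital filter, causally or with zero phase
#'
#' Zero-phase mode filters forward and backward so that the net response is
#' `|H|^2` with no group delay; the trace is extended at both ends by odd
#' reflection long enough for start-up transients to decay before they reach
#' the data.
#'
#' @param x Numeric sample vector.
#' @param b,a Filter coefficients.
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @return Filtered vector, same length as `x`.
#' @export
apply_filter <- function(x, b, a, zero_phase = TRUE) {
  n <- length(x)
  if (n == 0L) return(x)
  if (!zero_phase) return(lfilter(x, b, a))
  pad <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L),
                         settle_samples(a)))
  if (pad < 1L) return(lfilter(rev(lfilter(x, b, a)), b, a)[n:1])
  head_ext <- 2 * x[1] - x[(pad + 1L):2L]
  tail_ext <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- lfilter(c(head_ext, x, tail_ext), b, a)
  y <- rev(lfilter(rev(y), b, a))
  y[(pad + 1L):(pad + n)]
}
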