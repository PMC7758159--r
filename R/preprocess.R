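# Preprocessing of nerve channels: band-pass / notch filtering and
# rectified leaky integration, plus the per-bin blood-pressure summary.

#' Filter specification
#'
#' Describes one stage of the preprocessing chain. Two kinds are supported:
#' `"bandpass"` (Butterworth, `order` refers to the analog prototype, so the
#' digital filter has `2 * order` poles) and `"notch"` (second-order IIR,
#' bandwidth `center_hz / q_factor`). Filters are applied forward-backward
#' by default (zero phase) so detected event times are not delayed.
#'
#' The two stock chains used for nerve recordings are available as
#' [ssna_filter_specs()] (300-1000 Hz band-pass plus 50 Hz mains notch) and
#' [cvna_filter_specs()] (stricter 300-550 Hz band-pass, no notch).
#'
#' @param kind `"bandpass"` or `"notch"`.
#' @param low_hz,high_hz Band edges in Hz (band-pass only).
#' @param center_hz Notch center in Hz (notch only).
#' @param q_factor Notch quality factor; default 30.
#' @param order Prototype order for the band-pass; default 4.
#' @param zero_phase Apply forward-backward; default `TRUE`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("bandpass", "notch"), low_hz = NULL,
                        high_hz = NULL, center_hz = NULL, q_factor = 30,
                        order = 4, zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (kind == "bandpass") {
    if (is.null(low_hz) || is.null(high_hz) || !(low_hz > 0) ||
        !(low_hz < high_hz))
      stop("bandpass spec needs 0 < low_hz < high_hz", call. = FALSE)
  } else {
    if (is.null(center_hz) || !(center_hz > 0))
      stop("notch spec needs center_hz > 0", call. = FALSE)
    if (!(q_factor > 0)) stop("`q_factor` must be positive", call. = FALSE)
  }
  if (!(order >= 1)) stop("`order` must be >= 1", call. = FALSE)
  structure(list(kind = kind, low_hz = low_hz, high_hz = high_hz,
                 center_hz = center_hz, q_factor = q_factor, order = order,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
ssna_filter_specs <- function() {
  list(filter_spec("notch", center_hz = 50),
       filter_spec("bandpass", low_hz = 300, high_hz = 1000))
}

#' @rdname filter_spec
#' @export
cvna_filter_specs <- function() {
  list(filter_spec("bandpass", low_hz = 300, high_hz = 550))
}

filter_coefs <- function(spec, fs) {
  if (spec$kind == "bandpass") {
    if (!(spec$high_hz < fs / 2))
      stop("band edge ", spec$high_hz, " Hz at or above Nyquist (fs = ", fs,
           ")", call. = FALSE)
    butter_bandpass(spec$order, spec$low_hz, spec$high_hz, fs)
  } else {
    iir_notch(spec$center_hz, spec$q_factor, fs)
  }
}

#' Band-pass filter a trace
#'
#' @param trace Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param spec A `"bandpass"` [filter_spec()]; default is the 300-1000 Hz
#'   nerve band.
#' @return Filtered vector of the same length.
#' @export
bandpass_filter <- function(trace, fs,
                            spec = filter_spec("bandpass", low_hz = 300,
                                               high_hz = 1000)) {
  stopifnot(inherits(spec, "filter_spec"), spec$kind == "bandpass")
  co <- filter_coefs(spec, fs)
  apply_filter(as.numeric(trace), co$b, co$a, zero_phase = spec$zero_phase)
}

#' Notch filter a trace
#'
#' Removes narrow-band mains interference (50 Hz by default).
#'
#' @param trace Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param center_hz Notch center in Hz; default 50.
#' @param q_factor Quality factor; default 30.
#' @param zero_phase Apply forward-backward; default `TRUE`.
#' @return Filtered vector of the same length.
#' @export
notch_filter <- function(trace, fs, center_hz = 50, q_factor = 30,
                         zero_phase = TRUE) {
  co <- iir_notch(center_hz, q_factor, fs)
  apply_filter(as.numeric(trace), co$b, co$a, zero_phase = zero_phase)
}

#' Apply a chain of filter specs
#' @param trace Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param specs List of [filter_spec()] objects, applied in order.
#' @return Filtered vector.
#' @export
apply_filter_chain <- function(trace, fs, specs) {
  for (sp in specs) {
    co <- filter_coefs(sp, fs)
    trace <- apply_filter(as.numeric(trace), co$b, co$a,
                          zero_phase = sp$zero_phase)
  }
  trace
}

#' Full-wave rectify and leaky-integrate a trace
#'
#' Computes the envelope `y[n] = y[n-1] * d + |x[n]| * (1 - d)` with
#' `d = exp(-1 / (fs * tau))` and `y[-1] = 0`. The integrator is normalized
#' to unit DC gain, so a constant input converges to itself and envelope
#' values stay interpretable in the input units. A unit impulse decays by
#' `e^-1` over exactly `tau` seconds.
#'
#' @param trace Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param tau Decay time constant in seconds; default 0.1.
#' @return An object of class `integrated_trace` with fields `samples`
#'   (non-negative envelope, input units), `fs` and `tau`.
#' @export
rectify_integrate <- function(trace, fs, tau = 0.1) {
  if (!(is.numeric(tau) && length(tau) == 1L && tau > 0))
    stop("`tau` must be a positive number of seconds", call. = FALSE)
  if (!(fs > 0)) stop("`fs` must be positive", call. = FALSE)
  d <- exp(-1 / (fs * tau))
  y <- lfilter(abs(as.numeric(trace)), 1 - d, c(1, -d))
  structure(list(samples = y, fs = fs, tau = tau),
            class = "integrated_trace")
}

#' @export
print.integrated_trace <- function(x, ...) {
  cat(sprintf(
    "<integrated_trace> %d samples @ %g Hz, tau = %g s, max = %.3g\n",
    length(x$samples), x$fs, x$tau, max(x$samples)))
  invisible(x)
}

#' Per-bin blood-pressure stability summary
#'
#' Splits a blood-pressure trace into consecutive bins and reports mean and
#' standard deviation per complete bin, as a compact stability check of the
#' preparation. An incomplete trailing bin is not summarized; its length is
#' reported in the `incomplete_tail_s` attribute of the result.
#'
#' @param bp Blood-pressure sample vector (mmHg).
#' @param fs Sampling rate in Hz.
#' @param bin_s Bin length in seconds; default 600 (10 minutes).
#' @return Data frame with `bin_start`, `bin_len`, `mean`, `sd`.
#' @export
bp_bin_summary <- function(bp, fs, bin_s = 600) {
  if (length(bp) == 0L) stop("empty blood-pressure trace", call. = FALSE)
  if (!(bin_s > 0)) stop("`bin_s` must be positive", call. = FALSE)
  per <- round(bin_s * fs)
  nbin <- length(bp) %/% per
  out <- data.frame(bin_start = (seq_len(nbin) - 1) * bin_s,
                    bin_len = rep(bin_s, nbin),
                    mean = numeric(nbin), sd = numeric(nbin))
  for (i in seq_len(nbin)) {
    seg <- bp[((i - 1) * per + 1):(i * per)]
    out$mean[i] <- mean(seg)
    out$sd[i] <- stats::sd(seg)
  }
  attr(out, "incomplete_tail_s") <- (length(bp) - nbin * per) / fs
  out
}
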