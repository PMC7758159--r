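# Noise-floor estimation, spike detection and per-bin firing summaries for
# multi-unit sympathetic nerve activity.

#' Estimate the baseline noise floor from a spike-free segment
#'
#' The floor is a robust spread estimate (median absolute deviation scaled
#' to be consistent with the standard deviation under Gaussian noise) of a
#' spike-free stretch of the *filtered* trace -- in practice a post-mortem
#' segment, during which genuine nerve activity is absent. Robustness
#' matters because post-mortem stretches can still contain occasional
#' movement or electrical artifacts.
#'
#' @param trace Filtered sample vector (same preprocessing as the trace on
#'   which spikes will be detected).
#' @param fs Sampling rate in Hz.
#' @param segment One-row data frame with `t_start`, `t_end` (seconds,
#'   half-open) selecting the spike-free stretch, e.g. from
#'   [get_annotation()]; `NULL` uses the whole trace.
#' @return An object of class `noise_estimate` with fields `floor`
#'   (microvolts), `method`, `source_annotation` and `n_samples`.
#' @export
estimate_noise_floor <- function(trace, fs, segment = NULL) {
  if (is.null(segment)) {
    seg <- as.numeric(trace)
    lab <- "<whole trace>"
  } else {
    stopifnot(is.data.frame(segment), nrow(segment) == 1L)
    i0 <- round(segment$t_start * fs)
    i1 <- round(segment$t_end * fs)
    if (i0 < 0 || i1 > length(trace))
      stop("noise segment lies outside the trace", call. = FALSE)
    seg <- as.numeric(trace)[(i0 + 1L):i1]
    lab <- if ("label" %in% names(segment)) segment$label else "<segment>"
  }
  if (length(seg) < fs)
    stop("noise segment must be at least 1 s long", call. = FALSE)
  floor <- stats::mad(seg)
  if (floor == 0)
    warning("degenerate noise segment: estimated floor is 0", call. = FALSE)
  structure(list(floor = floor, method = "mad*1.4826",
                 source_annotation = lab, n_samples = length(seg)),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> floor = %.4g uV (%s, %d samples from %s)\n",
              x$floor, x$method, x$n_samples, x$source_annotation))
  invisible(x)
}

#' Detect spikes above a multiple of the noise floor
#'
#' Events are local maxima of the rectified trace `|x|` exceeding
#' `k * floor`, separated by at least the refractory period (enforced in
#' order of decreasing amplitude). Detection runs on the magnitude because
#' electrode polarity is arbitrary in extracellular recordings.
#'
#' @param trace Filtered sample vector.
#' @param fs Sampling rate in Hz.
#' @param noise A [estimate_noise_floor()] result, or a single positive
#'   number taken as the floor in the units of `trace`.
#' @param k Threshold multiplier (>= 1); default 3.
#' @param refractory_s Minimum separation between events in seconds;
#'   default 0.001 (1 ms, to avoid double-counting one deflection).
#' @return Data frame of spike events with columns `t` (seconds from trace
#'   start) and `peak` (`|trace|` at the event, microvolts).
#' @export
detect_spikes <- function(trace, fs, noise, k = 3, refractory_s = 0.001) {
  floor <- if (inherits(noise, "noise_estimate")) noise$floor else
    as.numeric(noise)
  if (!(is.finite(floor) && floor > 0))
    stop("noise floor must be positive: threshold undefined", call. = FALSE)
  if (!(k >= 1)) stop("`k` must be >= 1", call. = FALSE)
  if (!(refractory_s >= 0)) stop("`refractory_s` must be >= 0", call. = FALSE)
  a <- abs(as.numeric(trace))
  idx <- find_peaks(a, min_height = k * floor,
                    min_separation_n = round(refractory_s * fs))
  data.frame(t = (idx - 1L) / fs, peak = a[idx])
}

#' Count spikes per analysis bin
#'
#' Bins tile the half-open span `[t_span[1], t_span[2])`; a spike exactly on
#' a boundary belongs to the later bin. Only complete bins are returned.
#' Firing frequency is reported in the conventional unit of spikes per bin
#' (identical to the count), with a per-second rate as a convenience column.
#'
#' @param spikes Data frame from [detect_spikes()] (columns `t`, `peak`).
#' @param t_span Numeric length-2 vector, analysis span in seconds.
#' @param bin_s Bin length in seconds; default 600 (10 minutes).
#' @return Data frame with `bin_start`, `bin_len`, `n_spikes`,
#'   `firing_frequency` and `rate_hz`.
#' @export
bin_firing_frequency <- function(spikes, t_span, bin_s = 600) {
  if (!(bin_s > 0)) stop("`bin_s` must be positive", call. = FALSE)
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1])
  nbin <- floor((t_span[2] - t_span[1]) / bin_s + 1e-9)
  if (nbin < 1L) stop("span shorter than one bin", call. = FALSE)
  starts <- t_span[1] + (seq_len(nbin) - 1) * bin_s
  counts <- integer(nbin)
  if (nrow(spikes)) {
    tt <- spikes$t
    tt <- tt[tt >= t_span[1] & tt < t_span[1] + nbin * bin_s]
    if (length(tt)) {
      bin <- floor((tt - t_span[1]) / bin_s) + 1L
      tabbed <- tabulate(bin, nbins = nbin)
      counts <- tabbed
    }
  }
  data.frame(bin_start = starts, bin_len = bin_s, n_spikes = counts,
             firing_frequency = counts, rate_hz = counts / bin_s)
}

#' Mean spike amplitude relative to the noise floor
#'
#' The amplitude gain of a set of spikes is the mean over spikes of
#' `peak / floor`. For an empty set the gain is undefined and `NA` is
#' returned (not 0).
#'
#' @param spikes Data frame from [detect_spikes()].
#' @param noise A [estimate_noise_floor()] result or a positive number.
#' @return Dimensionless gain, or `NA_real_` when `spikes` is empty.
#' @export
amplitude_gain <- function(spikes, noise) {
  floor <- if (inherits(noise, "noise_estimate")) noise$floor else
    as.numeric(noise)
  if (!(is.finite(floor) && floor > 0))
    stop("noise floor must be positive", call. = FALSE)
  if (nrow(spikes) == 0L) return(NA_real_)
  mean(spikes$peak) / floor
}

#' Per-bin spike summary (counts and amplitude gain)
#'
#' Convenience wrapper combining [bin_firing_frequency()] with a per-bin
#' [amplitude_gain()].
#'
#' @inheritParams bin_firing_frequency
#' @inheritParams amplitude_gain
#' @return The [bin_firing_frequency()] frame with an `amplitude_gain`
#'   column (`NA` for bins without spikes).
#' @export
spike_bin_summary <- function(spikes, noise, t_span, bin_s = 600) {
  out <- bin_firing_frequency(spikes, t_span, bin_s)
  out$amplitude_gain <- vapply(seq_len(nrow(out)), function(i) {
    lo <- out$bin_start[i]
    sel <- spikes[spikes$t >= lo & spikes$t < lo + bin_s, , drop = FALSE]
    amplitude_gain(sel, noise)
  }, numeric(1))
  out
}
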