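# Burst quantification on the rectified-integrated (envelope) trace.
# Multi-unit "activation ensembles" appear as smooth envelope elevations;
# each ensemble is counted once, however many spikes it contains.

#' Detect peaks of an integrated trace above an envelope noise reference
#'
#' Local maxima of the envelope exceeding `k * noise_env`, separated by at
#' least `min_separation_s`. Plateau maxima are reported at their earliest
#' sample.
#'
#' @param env An `integrated_trace` from [rectify_integrate()] (or a plain
#'   numeric vector, in which case `fs` must be given).
#' @param noise_env Envelope noise reference in the envelope units, e.g.
#'   from [envelope_noise_ref()]; must be positive.
#' @param k Threshold multiplier; default 2.
#' @param min_separation_s Minimum peak separation in seconds; default
#'   equals the integrator time constant (0.1 s).
#' @param fs Sampling rate, only needed when `env` is a bare vector.
#' @return Data frame with columns `t` and `peak`.
#' @export
detect_integrated_peaks <- function(env, noise_env, k = 2,
                                    min_separation_s = 0.1, fs = NULL) {
  if (inherits(env, "integrated_trace")) {
    x <- env$samples
    fs <- env$fs
  } else {
    x <- as.numeric(env)
    if (is.null(fs)) stop("`fs` required for a bare vector", call. = FALSE)
  }
  if (!(is.finite(noise_env) && noise_env > 0))
    stop("`noise_env` must be positive", call. = FALSE)
  idx <- find_peaks(x, min_height = k * noise_env,
                    min_separation_n = round(min_separation_s * fs))
  data.frame(t = (idx - 1L) / fs, peak = x[idx])
}

#' Envelope noise reference from a spike-free segment
#'
#' Summarizes the envelope of a post-mortem (spike-free) recording by its
#' median, giving the envelope-domain analogue of the spike-domain noise
#' floor so both thresholds are referenced to the same baseline data.
#'
#' @param env An `integrated_trace` of the spike-free segment (or numeric
#'   vector).
#' @return Median envelope value (same units as the envelope).
#' @export
envelope_noise_ref <- function(env) {
  x <- if (inherits(env, "integrated_trace")) env$samples else as.numeric(env)
  if (length(x) == 0L) stop("empty envelope", call. = FALSE)
  stats::median(x)
}

#' Merge nearby envelope peaks into activation bursts
#'
#' Maximal groups of consecutive peaks whose inter-peak gaps are all
#' `<= merge_gap_s` become a single burst; the burst amplitude is the
#' largest member peak. With `merge_gap_s = 0` every peak is its own burst.
#'
#' @param peaks Time-sorted data frame with columns `t` and `peak`.
#' @param merge_gap_s Maximum inter-peak gap inside one burst, seconds;
#'   default 0.3 (three integrator time constants).
#' @return Data frame of bursts with `t_start`, `t_end`, `peak`, `n_peaks`.
#' @export
merge_peaks_to_bursts <- function(peaks, merge_gap_s = 0.3) {
  if (!(merge_gap_s >= 0)) stop("`merge_gap_s` must be >= 0", call. = FALSE)
  if (nrow(peaks) == 0L)
    return(data.frame(t_start = numeric(), t_end = numeric(),
                      peak = numeric(), n_peaks = integer()))
  if (is.unsorted(peaks$t))
    stop("`peaks` must be sorted by time", call. = FALSE)
  grp <- cumsum(c(TRUE, diff(peaks$t) > merge_gap_s))
  agg <- split(seq_len(nrow(peaks)), grp)
  data.frame(
    t_start = vapply(agg, function(i) peaks$t[i[1L]], numeric(1)),
    t_end = vapply(agg, function(i) peaks$t[i[length(i)]], numeric(1)),
    peak = vapply(agg, function(i) max(peaks$peak[i]), numeric(1)),
    n_peaks = vapply(agg, length, integer(1)),
    row.names = NULL)
}

#' Count bursts per analysis bin
#'
#' A burst is assigned to the bin containing its onset (`t_start`), so a
#' burst straddling a bin boundary is counted exactly once. Bins tile the
#' half-open span; only complete bins are returned.
#'
#' @param bursts Data frame from [merge_peaks_to_bursts()].
#' @param t_span Numeric length-2 vector, analysis span in seconds.
#' @param bin_s Bin length in seconds; default 600.
#' @return Data frame with `bin_start`, `bin_len`, `n_bursts`.
#' @export
bin_burst_count <- function(bursts, t_span, bin_s = 600) {
  if (!(bin_s > 0)) stop("`bin_s` must be positive", call. = FALSE)
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1])
  nbin <- floor((t_span[2] - t_span[1]) / bin_s + 1e-9)
  if (nbin < 1L) stop("span shorter than one bin", call. = FALSE)
  counts <- integer(nbin)
  if (nrow(bursts)) {
    tt <- bursts$t_start
    tt <- tt[tt >= t_span[1] & tt < t_span[1] + nbin * bin_s]
    if (length(tt))
      counts <- tabulate(floor((tt - t_span[1]) / bin_s) + 1L, nbins = nbin)
  }
  data.frame(bin_start = t_span[1] + (seq_len(nbin) - 1) * bin_s,
             bin_len = bin_s, n_bursts = counts)
}
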