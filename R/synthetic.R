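# Ground-truthed generators: synthetic multi-unit nerve recordings,
# post-mortem noise segments, per-animal group summaries and bimodal test
# images. Every generator is a pure function of (configuration, seed).

#' Synthetic recording configuration
#'
#' Describes the statistical world the simulator emulates: spikes organized
#' in burst ensembles (a homogeneous Poisson process of bursts, each with a
#' Poisson number of spikes fired at an intra-burst rate), biphasic spike
#' waveforms added onto broadband Gaussian noise plus a 50 Hz mains sine.
#' Defaults are chosen to resemble a rodent autonomic multi-unit
#' preparation: 4 kHz sampling, 2 uV RMS baseline noise, 20 uV spike peaks
#' (SNR 10), 2 ms biphasic spikes (fundamental 500 Hz, inside both the
#' 300-1000 Hz and the 300-550 Hz analysis bands), ~15 spikes per burst at
#' 150 Hz, 30 bursts per 10-minute bin, and a 5 uV mains component.
#'
#' @param fs Sampling rate in Hz; default 4000.
#' @param duration_s Recording length in seconds; default 600 (one
#'   analysis bin).
#' @param burst_rate Expected bursts per 600 s; default 30.
#' @param spikes_per_burst Mean spike count per burst (Poisson, bursts with
#'   zero draws are dropped); default 15.
#' @param intra_burst_rate Within-burst firing rate in Hz; default 150.
#' @param spike_peak Spike peak amplitude in uV; default 20.
#' @param spike_width_ms Biphasic spike width (one full cycle) in ms;
#'   default 2.
#' @param noise_sd Gaussian background noise SD in uV; default 2.
#' @param mains_amp Mains interference amplitude in uV; default 5.
#' @param mains_hz Mains frequency in Hz; default 50.
#' @param seed Integer seed fixing all randomness; default 1.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fs = 4000, duration_s = 600, burst_rate = 30,
                         spikes_per_burst = 15, intra_burst_rate = 150,
                         spike_peak = 20, spike_width_ms = 2, noise_sd = 2,
                         mains_amp = 5, mains_hz = 50, seed = 1L) {
  stopifnot(fs > 0, duration_s > 0, burst_rate >= 0, spikes_per_burst >= 0,
            intra_burst_rate >= 0, spike_peak >= 0, spike_width_ms > 0,
            noise_sd >= 0, mains_amp >= 0, mains_hz > 0)
  structure(as.list(environment()), class = "synth_config")
}

#' Biphasic spike template
#'
#' One full cycle of a sinusoid: positive lobe followed by a negative lobe,
#' zero net area, analytic peak equal to `peak` (the width is rounded to a
#' multiple of 4 samples so the discrete maximum hits the analytic one).
#'
#' @param peak Peak amplitude in uV.
#' @param width_ms Total width (one cycle) in ms.
#' @param fs Sampling rate in Hz.
#' @return Numeric template vector.
#' @export
spike_template <- function(peak, width_ms, fs) {
  w <- max(4L, 4L * round(width_ms / 1000 * fs / 4))
  peak * sin(2 * pi * (0:(w - 1L)) / w)
}

#' Add spike templates to a trace at given times
#'
#' @param trace Numeric sample vector (modified copy returned).
#' @param times Spike onset times in seconds.
#' @param template Waveform from [spike_template()].
#' @param fs Sampling rate in Hz.
#' @return The trace with templates summed in (templates running off the
#'   end are truncated).
#' @export
inject_spikes <- function(trace, times, template, fs) {
  n <- length(trace)
  w <- length(template)
  for (t in times) {
    i0 <- round(t * fs) + 1L
    if (i0 > n) next
    i1 <- min(i0 + w - 1L, n)
    trace[i0:i1] <- trace[i0:i1] + template[seq_len(i1 - i0 + 1L)]
  }
  trace
}

synth_background <- function(cfg) {
  n <- round(cfg$duration_s * cfg$fs)
  tt <- (0:(n - 1L)) / cfg$fs
  stats::rnorm(n, sd = cfg$noise_sd) +
    cfg$mains_amp * sin(2 * pi * cfg$mains_hz * tt)
}

#' Simulate a ground-truthed multi-unit nerve recording
#'
#' Bursts are drawn as a homogeneous Poisson process at `burst_rate` per
#' 600 s; each burst fires `Poisson(spikes_per_burst)` spikes (bursts with
#' zero spikes are dropped) with exponential inter-spike intervals at
#' `intra_burst_rate`. Spike templates are added to Gaussian noise plus the
#' mains sine. A synthetic blood-pressure channel (stable mean 100 mmHg
#' with a cardiac oscillation) is included so per-bin stability summaries
#' can be exercised.
#'
#' @param cfg A [synth_config()].
#' @return List with `recording` (a [recording()] with channels `nerve`
#'   and `bp`) and `truth` (list of `spike_times` and `burst_intervals`, a
#'   data frame with `t_start`, `t_end`).
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$duration_s < 600)
    warning("duration shorter than one 600 s analysis bin", call. = FALSE)
  set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  nerve <- synth_background(cfg)
  n_bursts <- stats::rpois(1, cfg$burst_rate * cfg$duration_s / 600)
  spike_times <- numeric()
  intervals <- data.frame(t_start = numeric(), t_end = numeric())
  if (n_bursts > 0 && cfg$spikes_per_burst > 0) {
    onsets <- sort(stats::runif(n_bursts, 0, cfg$duration_s))
    tmpl <- spike_template(cfg$spike_peak, cfg$spike_width_ms, cfg$fs)
    st <- vector("list", n_bursts)
    keep <- logical(n_bursts)
    ends <- onsets
    for (i in seq_len(n_bursts)) {
      nk <- stats::rpois(1, cfg$spikes_per_burst)
      if (nk == 0) next
      gaps <- if (nk > 1) stats::rexp(nk - 1, cfg$intra_burst_rate) else
        numeric()
      tk <- onsets[i] + c(0, cumsum(gaps))
      tk <- tk[tk < cfg$duration_s]
      if (!length(tk)) next
      keep[i] <- TRUE
      st[[i]] <- tk
      ends[i] <- max(tk) + cfg$spike_width_ms / 1000
    }
    if (any(keep)) {
      spike_times <- unlist(st[keep])
      intervals <- data.frame(t_start = onsets[keep],
                              t_end = pmin(ends[keep], cfg$duration_s))
      nerve <- inject_spikes(nerve, spike_times, tmpl, cfg$fs)
    }
  }
  tt <- (0:(n - 1L)) / cfg$fs
  bp <- 100 + 8 * sin(2 * pi * 10 * tt) + stats::rnorm(n, sd = 0.5)
  rec <- recording(list(nerve = nerve, bp = bp), fs = cfg$fs,
                   units = c(nerve = "uV", bp = "mmHg"))
  list(recording = rec,
       truth = list(spike_times = spike_times, burst_intervals = intervals))
}

#' Simulate a post-mortem (spike-free) recording
#'
#' Background noise plus mains only, annotated `"postmortem"` over its full
#' extent, for use as the noise-floor reference.
#'
#' @param cfg A [synth_config()]; only the background fields are used.
#' @return A [recording()] with a single `nerve` channel.
#' @export
simulate_postmortem <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  nerve <- synth_background(cfg)
  recording(list(nerve = nerve), fs = cfg$fs,
            annotations = annotation("postmortem", 0, cfg$duration_s))
}

#' Simulate per-animal group summary values
#'
#' Draws Gaussian per-animal measurements for each group of a design, as a
#' stand-in for per-mouse firing-frequency or burst-count summaries.
#'
#' @param design Data frame with columns `group`, `n`, `mean`, `sd`
#'   (`n >= 2`, `sd >= 0`). Optional columns `factor_a` and `factor_b`
#'   are carried through for two-way designs.
#' @param seed Integer seed.
#' @return Data frame with `animal`, `group`, `value` (plus any carried
#'   factor columns).
#' @export
simulate_group_summaries <- function(design, seed = 1L) {
  stopifnot(is.data.frame(design),
            all(c("group", "n", "mean", "sd") %in% names(design)))
  if (any(design$n < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(design$sd < 0)) stop("`sd` must be >= 0", call. = FALSE)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    out <- data.frame(animal = paste0(d$group, "_", seq_len(d$n)),
                      group = d$group,
                      value = stats::rnorm(d$n, d$mean, d$sd))
    for (f in intersect(c("factor_a", "factor_b"), names(design)))
      out[[f]] <- d[[f]]
    out
  })
  do.call(rbind, rows)
}

#' Simulate a bimodal grayscale immunofluorescence-like image
#'
#' Foreground blobs are obtained by thresholding a smoothed Gaussian random
#' field at the quantile giving the requested coverage, so the true mask
#' fraction matches `target_fraction` up to pixel quantization. Foreground
#' and background intensities differ by `fg_mean - bg_mean` with additive
#' Gaussian noise, giving a bimodal intensity histogram.
#'
#' @param width,height Image size in pixels.
#' @param target_fraction Fraction of foreground pixels, in (0, 1).
#' @param fg_mean,bg_mean Mean foreground / background intensity
#'   (`fg_mean > bg_mean`).
#' @param noise_sd Intensity noise SD.
#' @param seed Integer seed.
#' @param blob_scale Smoothing length of the random field in pixels
#'   (controls blob size); default one tenth of the smaller image side.
#' @return List with `image` (numeric `height x width` matrix) and `mask`
#'   (logical matrix, `TRUE` = foreground).
#' @export
simulate_if_image <- function(width, height, target_fraction, fg_mean,
                              bg_mean, noise_sd, seed = 1L,
                              blob_scale = NULL) {
  if (!(target_fraction > 0 && target_fraction < 1))
    stop("`target_fraction` must be in (0, 1)", call. = FALSE)
  if (!(fg_mean > bg_mean)) stop("`fg_mean` must exceed `bg_mean`",
                                 call. = FALSE)
  set.seed(seed)
  if (is.null(blob_scale)) blob_scale <- max(2, round(min(width, height) / 10))
  field <- matrix(stats::rnorm(width * height), height, width)
  kern <- stats::dnorm(seq(-2, 2, length.out = 2 * blob_scale + 1))
  kern <- kern / sum(kern)
  smooth1 <- function(m) t(apply(m, 1, function(r)
    stats::filter(c(rev(r[seq_len(blob_scale)]), r,
                    rev(r[(length(r) - blob_scale + 1):length(r)])),
                  kern, sides = 2)[(blob_scale + 1):(blob_scale + length(r))]))
  field <- t(smooth1(t(smooth1(field))))
  thr <- stats::quantile(field, 1 - target_fraction, names = FALSE)
  mask <- field > thr
  img <- bg_mean + (fg_mean - bg_mean) * mask +
    matrix(stats::rnorm(width * height, sd = noise_sd), height, width)
  list(image = img, mask = mask)
}
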