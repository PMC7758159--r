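# Vagus nerve stimulation protocol: representation, schedule construction,
# pulse-train rendering, analysis-window convention and artifact blanking.

#' Stimulation protocol
#'
#' The default protocol alternates one minute of stimulation with one
#' minute off across a 10-minute window: 5 Hz trains of monophasic 0.3 mA
#' pulses during the ON minutes. The phase convention (first minute ON) and
#' the pulse width are configurable; neither affects the downstream
#' analysis windows. `mode = "sham"` keeps the stimulator off while
#' preserving the timeline.
#'
#' @param pulse_rate Pulse rate in Hz during ON intervals; default 5.
#' @param pulse_amplitude Pulse amplitude in mA; default 0.3.
#' @param pulse_width Pulse width in seconds; default 0.001.
#' @param on_s ON time per cycle in seconds; default 60.
#' @param period_s Cycle period in seconds; default 120.
#' @param window_s Total stimulation window in seconds; default 600.
#' @param mode `"vns"` or `"sham"`.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(pulse_rate = 5, pulse_amplitude = 0.3,
                          pulse_width = 0.001, on_s = 60, period_s = 120,
                          window_s = 600, mode = c("vns", "sham")) {
  mode <- match.arg(mode)
  if (!(pulse_rate > 0)) stop("`pulse_rate` must be positive", call. = FALSE)
  if (!(pulse_amplitude > 0)) stop("`pulse_amplitude` must be positive",
                                   call. = FALSE)
  if (!(pulse_width > 0)) stop("`pulse_width` must be positive",
                               call. = FALSE)
  if (!(on_s > 0 && on_s <= period_s))
    stop("need 0 < on_s <= period_s", call. = FALSE)
  if (!(window_s >= on_s && abs(window_s / period_s -
                                round(window_s / period_s)) < 1e-9))
    stop("`window_s` must be a multiple of `period_s` and >= `on_s`",
         call. = FALSE)
  structure(list(pulse_rate = pulse_rate, pulse_amplitude = pulse_amplitude,
                 pulse_shape = "monophasic", pulse_width = pulse_width,
                 on_s = on_s, period_s = period_s, window_s = window_s,
                 mode = mode),
            class = "stim_protocol")
}

#' Build the ON-interval and pulse-time schedule of a protocol
#'
#' In `"vns"` mode the stimulation window is tiled by cycles starting ON
#' (so the default yields ON intervals `[0,60)`, `[120,180)`, ...,
#' `[480,540)`), with pulses at the pulse rate from the start of each ON
#' interval. In `"sham"` mode the schedule is empty.
#'
#' @param p A [stim_protocol()].
#' @return An object of class `stim_schedule` with `on_intervals` (data
#'   frame `t_start`, `t_end`) and `pulse_times` (seconds).
#' @export
build_schedule <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  if (p$mode == "sham") {
    sched <- list(on_intervals = data.frame(t_start = numeric(),
                                            t_end = numeric()),
                  pulse_times = numeric())
  } else {
    starts <- seq(0, p$window_s - p$period_s, by = p$period_s)
    per_on <- floor(p$on_s * p$pulse_rate - 1e-9) + 1L # pulses in [0, on_s)
    pulses <- as.vector(vapply(starts, function(s)
      s + (seq_len(per_on) - 1) / p$pulse_rate, numeric(per_on)))
    sched <- list(on_intervals = data.frame(t_start = starts,
                                            t_end = starts + p$on_s),
                  pulse_times = pulses)
  }
  structure(sched, class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> %d ON interval(s), %d pulse(s)\n",
              nrow(x$on_intervals), length(x$pulse_times)))
  invisible(x)
}

#' Render a stimulation schedule as a sampled current trace
#'
#' @param s A [build_schedule()] result.
#' @param p The [stim_protocol()] it was built from.
#' @param fs Sampling rate in Hz; `pulse_width` must be at least one
#'   sample.
#' @param duration_s Length of the rendered trace in seconds; defaults to
#'   the protocol window.
#' @return Numeric vector in mA: `pulse_amplitude` during pulses (pulses
#'   are monophasic, so the trace is non-negative), 0 elsewhere.
#' @export
render_pulse_train <- function(s, p, fs, duration_s = p$window_s) {
  stopifnot(inherits(s, "stim_schedule"), inherits(p, "stim_protocol"))
  if (p$pulse_width < 1 / fs)
    stop("`pulse_width` shorter than one sample at fs = ", fs, call. = FALSE)
  if (p$pulse_width >= 1 / p$pulse_rate)
    stop("pulses overlap: width >= inter-pulse interval", call. = FALSE)
  n <- round(duration_s * fs)
  out <- numeric(n)
  w <- round(p$pulse_width * fs)
  for (t in s$pulse_times) {
    i0 <- round(t * fs) + 1L
    i1 <- min(i0 + w - 1L, n)
    if (i0 <= n) out[i0:i1] <- p$pulse_amplitude
  }
  out
}

#' Common analysis window after the stimulation window
#'
#' Both the stimulated and the sham timeline are analyzed over the same
#' 10-minute window following the stimulation period, i.e. minutes 10-20.
#'
#' @param mode `"vns"` or `"sham"` (the window is identical for both).
#' @return Numeric `c(t_start, t_end)` in seconds: `c(600, 1200)`.
#' @export
analysis_window <- function(mode = c("vns", "sham")) {
  match.arg(mode)
  c(600, 1200)
}

#' Blank stimulation artifacts out of a trace
#'
#' Replaces the samples within `blank_ms` after each pulse onset by linear
#' interpolation between the samples bounding the blanked stretch. The
#' operation preserves trace length, leaves a constant trace unchanged and
#' is idempotent.
#'
#' @param trace Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param s A [build_schedule()] result.
#' @param blank_ms Blanking window after each pulse, in milliseconds;
#'   default 2.
#' @return Blanked vector, same length as `trace`.
#' @export
blank_artifacts <- function(trace, fs, s, blank_ms = 2) {
  stopifnot(inherits(s, "stim_schedule"))
  if (!(blank_ms >= 0)) stop("`blank_ms` must be >= 0", call. = FALSE)
  x <- as.numeric(trace)
  n <- length(x)
  w <- round(blank_ms / 1000 * fs)
  if (w == 0L || length(s$pulse_times) == 0L) return(x)
  for (t in s$pulse_times) {
    i0 <- round(t * fs) + 1L
    if (i0 > n) next
    i1 <- min(i0 + w - 1L, n)
    lo <- if (i0 > 1L) x[i0 - 1L] else x[min(i1 + 1L, n)]
    hi <- if (i1 < n) x[i1 + 1L] else lo
    k <- i0:i1
    x[k] <- lo + (hi - lo) * (k - (i0 - 1L)) / (i1 + 1L - (i0 - 1L))
  }
  x
}
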