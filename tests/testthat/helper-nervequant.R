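# Shared test utilities.

make_sine <- function(freq, fs, dur_s, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(round(dur_s * fs) - 1)) / fs + phase)
}

# Steady-state RMS gain of a filtering function on a pure tone, measured on
# the central portion of a long sine: an oracle for frequency response that
# is independent of the analytic polynomial evaluation.
tone_gain <- function(filter_fun, freq, fs, dur_s = 4) {
  x <- make_sine(freq, fs, dur_s)
  y <- filter_fun(x)
  n <- length(x)
  core <- round(n * 0.25):round(n * 0.75)
  sqrt(mean(y[core]^2) / mean(x[core]^2))
}

db <- function(g) 20 * log10(g)

# A small recording fixture: two channels, optional annotations.
toy_recording <- function(n = 8, fs = 4000, ann = NULL) {
  recording(list(nerve = sin(seq_len(n)), bp = 100 + cos(seq_len(n))),
            fs = fs, units = c(nerve = "uV", bp = "mmHg"),
            annotations = ann)
}

# Brute-force reference for the intermodes procedure, written independently
# of the package implementation (explicit loops, explicit mode scan).
intermodes_oracle <- function(counts, max_iter = 10000) {
  h <- as.numeric(counts)
  modes_of <- function(v) {
    n <- length(v)
    found <- integer()
    i <- 1
    while (i <= n) {
      j <- i
      while (j < n && v[j + 1] == v[i]) j <- j + 1
      left <- if (i == 1) -Inf else v[i - 1]
      right <- if (j == n) -Inf else v[j + 1]
      if (v[i] > left && v[i] > right) found <- c(found, i)
      i <- j + 1
    }
    found
  }
  for (it in 0:max_iter) {
    m <- modes_of(h)
    if (length(m) == 2) return(floor((m[1] - 1 + m[2] - 1) / 2))
    if (length(m) < 2) stop("oracle: not bimodal")
    hs <- numeric(length(h))
    for (i in seq_along(h)) {
      lo <- if (i > 1) h[i - 1] else 0
      hi <- if (i < length(h)) h[i + 1] else 0
      hs[i] <- (lo + h[i] + hi) / 3
    }
    h <- hs
  }
  stop("oracle: iteration cap reached")
}

# Match detected event times against ground truth within a tolerance;
# returns recall and precision.
match_events <- function(detected, truth, tol_s = 0.002) {
  if (length(detected) == 0)
    return(list(recall = 0, precision = NA_real_))
  used <- logical(length(detected))
  hit <- 0L
  for (t in truth) {
    d <- abs(detected - t)
    d[used] <- Inf
    i <- which.min(d)
    if (length(i) && d[i] <= tol_s) {
      used[i] <- TRUE
      hit <- hit + 1L
    }
  }
  list(recall = hit / length(truth), precision = sum(used) / length(detected))
}
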