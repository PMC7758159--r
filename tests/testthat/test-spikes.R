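# Noise floor, spike detection, binning, amplitude gain.

test_that("noise floor recovers the SD of Gaussian noise", {
  set.seed(21)
  fs <- 4000
  x <- rnorm(60 * fs, sd = 2)
  nf <- estimate_noise_floor(x, fs)
  expect_s3_class(nf, "noise_estimate")
  expect_lt(abs(nf$floor - 2) / 2, 0.05)
  expect_equal(nf$n_samples, 60 * fs)
})

test_that("noise floor is robust to outliers, unlike the SD", {
  set.seed(22)
  fs <- 4000
  x <- rnorm(10 * fs, sd = 2)
  x_out <- x
  x_out[1000] <- 1e4
  clean <- estimate_noise_floor(x, fs)$floor
  dirty <- estimate_noise_floor(x_out, fs)$floor
  expect_lt(abs(dirty - clean) / clean, 1e-3)
  expect_gt(sd(x_out) / sd(x), 5) # the non-robust oracle blows up
})

test_that("noise floor respects the annotation segment and degenerate input", {
  fs <- 100
  x <- c(rnorm(2 * fs, sd = 5), rep(0, 2 * fs))
  seg <- annotation("postmortem", 2, 4)
  expect_warning(nf <- estimate_noise_floor(x, fs, seg), "degenerate")
  expect_equal(nf$floor, 0)
  expect_equal(nf$source_annotation, "postmortem")
  expect_error(estimate_noise_floor(x, fs, annotation("s", 0, 0.5)), "1 s")
  expect_error(estimate_noise_floor(x, fs, annotation("s", 3, 7)),
               "outside")
})

test_that("detect_spikes finds clean template spikes and respects k", {
  fs <- 4000
  set.seed(23)
  noise <- rnorm(60 * fs, sd = 1)
  truth <- seq(0.5, 59.5, length.out = 50)
  tmpl <- spike_template(10, 2, fs)
  x <- inject_spikes(noise, truth, tmpl, fs)
  nf <- estimate_noise_floor(noise, fs)
  # refractory matched to the 2 ms template so one deflection (two lobes
  # of the biphasic waveform) is counted once
  sp <- detect_spikes(x, fs, nf, k = 6, refractory_s = 0.002)
  m <- match_events(sp$t, truth + 0.0005, tol_s = 0.002)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  # monotonicity: raising k never increases the count
  ks <- c(3, 4, 6, 8, 11)
  counts <- vapply(ks, function(k)
    nrow(detect_spikes(x, fs, nf, k = k)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  # k above max|trace|/floor yields nothing
  expect_equal(nrow(detect_spikes(x, fs, nf,
                                  k = max(abs(x)) / nf$floor + 1)), 0)
  expect_error(detect_spikes(x, fs, 0), "positive")
})

test_that("detect_spikes is scale-equivariant", {
  fs <- 4000
  set.seed(24)
  x <- inject_spikes(rnorm(10 * fs), seq(1, 9, by = 0.5),
                     spike_template(8, 2, fs), fs)
  s1 <- detect_spikes(x, fs, 1, k = 4)
  s2 <- detect_spikes(7 * x, fs, 7, k = 4)
  expect_equal(s1$t, s2$t)
  expect_equal(7 * s1$peak, s2$peak)
})

test_that("refractory enforcement keeps the larger of two close peaks", {
  fs <- 1000
  x <- rep(0, fs)
  x[100] <- 5; x[102] <- 8 # 2 ms apart
  sp <- detect_spikes(x, fs, 1, k = 3, refractory_s = 0.005)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$peak, 8)
  sp2 <- detect_spikes(x, fs, 1, k = 3, refractory_s = 0.001)
  expect_equal(nrow(sp2), 2)
})

test_that("binning conserves counts and uses half-open bins", {
  spikes <- data.frame(t = c(0, 100, 599.999, 600, 700, 1199.9),
                       peak = rep(1, 6))
  b <- bin_firing_frequency(spikes, c(0, 1200), bin_s = 600)
  expect_equal(b$n_spikes, c(3, 3))
  expect_equal(b$firing_frequency, b$n_spikes)
  expect_equal(sum(b$n_spikes), nrow(spikes))
  # spike exactly on the boundary goes to the later bin
  b2 <- bin_firing_frequency(data.frame(t = 600, peak = 1), c(0, 1200), 600)
  expect_equal(b2$n_spikes, c(0, 1))
  # empty spike list
  b3 <- bin_firing_frequency(data.frame(t = numeric(), peak = numeric()),
                             c(0, 1200), 600)
  expect_equal(b3$n_spikes, c(0, 0))
  expect_error(bin_firing_frequency(spikes, c(0, 1200), bin_s = 0), "bin_s")
})

test_that("conservation holds on random spike sets", {
  set.seed(25)
  for (rep in 1:5) {
    tt <- sort(runif(300, 0, 3000))
    spikes <- data.frame(t = tt, peak = runif(300, 1, 5))
    b <- bin_firing_frequency(spikes, c(0, 3000), bin_s = 600)
    expect_equal(sum(b$n_spikes), sum(tt < 3000))
  }
})

test_that("amplitude gain is the mean peak-to-floor ratio", {
  nf <- structure(list(floor = 2), class = "noise_estimate")
  expect_equal(amplitude_gain(data.frame(t = 1:3, peak = rep(10, 3)), nf), 5)
  expect_equal(amplitude_gain(data.frame(t = 1:2, peak = c(4, 8)), nf), 3)
  expect_true(is.na(amplitude_gain(data.frame(t = numeric(),
                                              peak = numeric()), nf)))
  s <- spike_bin_summary(data.frame(t = c(10, 20), peak = c(4, 8)), nf,
                         c(0, 1200), 600)
  expect_equal(s$amplitude_gain, c(3, NA_real_))
  expect_equal(s$n_spikes, c(2, 0))
})
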