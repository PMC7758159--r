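# Filtering and rectified leaky integration.

test_that("band-pass design matches an independent reference", {
  # coefficients of the default 300-1000 Hz design at fs 4000, computed
  # with an independent implementation of the bilinear-transform
  # Butterworth construction (frozen)
  co <- butter_bandpass(4, 300, 1000, 4000)
  b_ref <- c(0.0304852698491542, 0, -0.12194107939661679, 0,
             0.18291161909492518, 0, -0.12194107939661679, 0,
             0.0304852698491542)
  a_ref <- c(1, -3.1713210694525067, 5.099745015008548, -5.524043138420596,
             4.47740850733699, -2.6597791161304696, 1.1151289621300715,
             -0.307057047162381, 0.04766255662918978)
  expect_equal(co$b, b_ref, tolerance = 1e-12)
  expect_equal(co$a, a_ref, tolerance = 1e-12)
})

test_that("band-pass passes in-band tones and rejects out-of-band tones", {
  fs <- 4000
  bp <- function(x) bandpass_filter(x, fs)
  # time-domain oracle
  expect_gte(tone_gain(bp, 650, fs), 0.9)
  expect_lte(db(tone_gain(bp, 10, fs)), -20)
  # analytic oracle (zero-phase net response is |H|^2)
  co <- butter_bandpass(4, 300, 1000, fs)
  H <- abs(filter_response(co$b, co$a, c(10, 650), fs))^2
  expect_lte(db(H[1]), -20)
  expect_gte(H[2], 0.9)
  # the two routes agree
  expect_equal(tone_gain(bp, 650, fs), H[2], tolerance = 1e-3)
  expect_equal(bp(rep(0, 1000)), rep(0, 1000))
  expect_error(bandpass_filter(rnorm(10), fs,
                               filter_spec("bandpass", low_hz = 300,
                                           high_hz = 2500)),
               "Nyquist")
})

test_that("notch kills the mains tone and spares neighbours", {
  fs <- 4000
  nf <- function(x) notch_filter(x, fs)
  expect_lte(db(tone_gain(nf, 50, fs, dur_s = 8)), -20)
  expect_lt(abs(db(tone_gain(nf, 400, fs))), 1)
  co <- iir_notch(50, 30, fs)
  expect_lte(db(abs(filter_response(co$b, co$a, 50, fs))^2), -20)
  expect_lt(abs(db(abs(filter_response(co$b, co$a, 150, fs))^2)), 1)
  expect_equal(nf(rep(0, 100)), rep(0, 100))
})

test_that("filters are linear and zero-phase introduces no lag", {
  fs <- 4000
  set.seed(11)
  x <- rnorm(4000)
  y <- rnorm(4000)
  lhs <- bandpass_filter(2 * x + 3 * y, fs)
  rhs <- 2 * bandpass_filter(x, fs) + 3 * bandpass_filter(y, fs)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  # broadband probe: zero-phase output aligns with the input at lag 0,
  # causal output does not (group delay); a sine would be lag-ambiguous
  set.seed(12)
  w <- rnorm(2 * fs)
  f <- bandpass_filter(w, fs)
  cc <- stats::ccf(f, w, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(abs(cc$acf))], 0)
  fc <- bandpass_filter(w, fs, filter_spec("bandpass", low_hz = 300,
                                           high_hz = 1000,
                                           zero_phase = FALSE))
  cc2 <- stats::ccf(fc, w, lag.max = 20, plot = FALSE)
  expect_false(cc2$lag[which.max(abs(cc2$acf))] == 0)
})

test_that("rectify_integrate follows the stated recursion", {
  fs <- 4000
  tau <- 0.1
  x <- c(1, rep(0, 2 * fs))
  env <- rectify_integrate(x, fs, tau)
  expect_s3_class(env, "integrated_trace")
  # e-fold decay over exactly tau seconds
  expect_equal(env$samples[1 + round(tau * fs)] / env$samples[1], exp(-1),
               tolerance = 1e-6)
  # constant input converges to itself (unit DC gain)
  cst <- rectify_integrate(rep(3.5, round(10 * tau * fs)), fs, tau)
  expect_equal(cst$samples[length(cst$samples)], 3.5, tolerance = 1e-3)
  n10 <- round(10 * tau * fs)
  expect_equal(cst$samples[n10], 3.5 * (1 - exp(-1 / (fs * tau))^n10),
               tolerance = 1e-12) # closed form of the recursion
  expect_true(all(env$samples >= 0))
  expect_error(rectify_integrate(x, fs, tau = -1), "tau")
})

test_that("rectification is sign-invariant and envelope is monotone in |x|", {
  fs <- 4000
  set.seed(5)
  x <- rnorm(4000)
  e1 <- rectify_integrate(x, fs)$samples
  e2 <- rectify_integrate(-x, fs)$samples
  expect_equal(e1, e2)
  bigger <- x * ifelse(seq_along(x) %% 2 == 0, 2, 1)
  e3 <- rectify_integrate(bigger, fs)$samples
  expect_true(all(e3 >= e1 - 1e-12))
})

test_that("bp_bin_summary summarizes complete bins only", {
  fs <- 100
  expect_error(bp_bin_summary(numeric(), fs), "empty")
  const <- rep(100, 20 * 60 * fs)
  s <- bp_bin_summary(const, fs, bin_s = 600)
  expect_equal(nrow(s), 2)
  expect_equal(s$mean, c(100, 100))
  expect_equal(s$sd, c(0, 0))
  expect_equal(attr(s, "incomplete_tail_s"), 0)
  # sine of amplitude a has sd a/sqrt(2)
  a <- 7
  x <- 90 + make_sine(2, fs, 600, amp = a)
  s2 <- bp_bin_summary(x, fs, bin_s = 600)
  expect_equal(s2$sd, a / sqrt(2), tolerance = 0.01)
  expect_equal(s2$mean, 90, tolerance = 1e-6)
  # trailing partial bin flagged, not summarized
  s3 <- bp_bin_summary(rep(1, 650 * fs), fs, bin_s = 600)
  expect_equal(nrow(s3), 1)
  expect_equal(attr(s3, "incomplete_tail_s"), 50)
})
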