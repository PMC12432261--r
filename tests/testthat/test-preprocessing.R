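test_that("band-pass obeys its stop- and pass-band contract", {
  fs <- 125
  n <- fs * 60
  t <- (seq_len(n) - 1) / fs
  mid <- (fs * 20):(fs * 40)

  dc <- bandpass(rep(100, n), fs)
  expect_lt(max(abs(dc[mid])), 1)

  y1 <- bandpass(sin(2 * pi * 1 * t), fs)
  amp1 <- (max(y1[mid]) - min(y1[mid])) / 2
  expect_gt(amp1, 0.95)
  expect_lt(amp1, 1.05)
  # zero-phase application squares the single-pass magnitude response
  expect_equal(amp1, butterworth_bandpass_gain(1, fs)^2, tolerance = 0.02)

  y50 <- bandpass(sin(2 * pi * 50 * t), fs)
  amp50 <- max(abs(y50[mid]))
  expect_lt(amp50, 0.02)
  # the analytic stop-band response is far below the measured residue,
  # which is edge-transient leakage, so it must respect the same bound
  expect_lt(butterworth_bandpass_gain(50, fs)^2, 1e-8)

  expect_error(bandpass(rnorm(100), 125, high_hz = 70), "Nyquist")
  expect_error(bandpass(rnorm(100), 125, low_hz = 0), "band edges")
  expect_error(bandpass(rnorm(10), 125), "too short")
})

test_that("band-pass filtering is linear", {
  set.seed(4)
  x <- rnorm(1000)
  y <- rnorm(1000)
  lhs <- bandpass(2 * x - 3 * y, 125)
  rhs <- 2 * bandpass(x, 125) - 3 * bandpass(y, 125)
  expect_lt(max(abs(lhs - rhs)), 1e-6)
})

test_that("linear detrending removes exactly the fitted line", {
  t <- seq_len(500)
  expect_lt(max(abs(detrend_linear(3 + 0.25 * t))), 1e-9)

  # output always has zero mean and zero least-squares slope
  set.seed(20)
  y <- detrend_linear(rnorm(500) + 0.3 * t)
  expect_lt(abs(mean(y)), 1e-10)
  expect_lt(abs(sum((t - mean(t)) * y)) / sum((t - mean(t))^2), 1e-12)

  # idempotent: a trend-free series passes through unchanged
  sine_perp <- detrend_linear(sin(2 * pi * 3 * (t - 1) / 500))
  expect_lt(max(abs(detrend_linear(sine_perp) - sine_perp)), 1e-9)

  # additive trends never leak into the oscillatory part
  sine <- sin(2 * pi * 3 * (t - 1) / 500)
  mixed <- sine + 2 - 0.01 * t
  expect_lt(max(abs(detrend_linear(mixed) - detrend_linear(sine))), 1e-9)

  expect_error(detrend_linear(1), "at least 2")
})

test_that("mean filter is a truncated centered box average", {
  expect_equal(mean_filter(rep(7, 100), 50), rep(7, 100))

  x <- numeric(301)
  x[151] <- 1
  mf <- mean_filter(x, 50)
  expect_equal(sum(mf > 1e-12), 50)
  expect_equal(max(mf), 1 / 50, tolerance = 1e-12)

  set.seed(5)
  v <- var(mean_filter(rnorm(1e4), 50))
  expect_lt(abs(v - 1 / 50), 0.3 / 50)

  expect_error(mean_filter(1:10, 0), "positive")
})

test_that("normalization maps onto [-1, 1] and flags constants", {
  expect_equal(as.numeric(normalize_unit(c(0, 2, 4))), c(-1, 0, 1))

  x <- sin(2 * pi * (0:15) / 16)  # attains exactly +1 and -1
  expect_lt(max(abs(normalize_unit(x) - x)), 1e-9)

  flat <- normalize_unit(c(5, 5, 5))
  expect_equal(as.numeric(flat), c(0, 0, 0))
  expect_true(is_degenerate(flat))
  expect_false(is_degenerate(normalize_unit(c(0, 1))))

  set.seed(6)
  for (i in 1:5) {
    y <- normalize_unit(rnorm(50))
    expect_true(min(y) == -1 && max(y) == 1)
  }
  expect_error(normalize_unit(1), "at least 2")
})

test_that("gap interpolation restores linear segments and edge values", {
  ramp <- seq(0, 10, length.out = 21)
  tr <- gaze_trace(replace(ramp, 8:10, NA), ramp * 0.5,
                   valid = !(seq_along(ramp) %in% 8:10), sample_rate_hz = 60)
  filled <- interpolate_missing(tr)
  expect_equal(filled$horizontal_deg, ramp, tolerance = 1e-12)
  expect_true(all(filled$valid))

  intact <- gaze_trace(ramp, ramp, sample_rate_hz = 60)
  expect_equal(interpolate_missing(intact)$horizontal_deg, ramp)

  lead <- gaze_trace(c(NA, NA, 3, 4), valid = c(FALSE, FALSE, TRUE, TRUE),
                     sample_rate_hz = 60)
  expect_equal(interpolate_missing(lead)$horizontal_deg, c(3, 3, 3, 4))

  one <- gaze_trace(c(NA, 2, NA), valid = c(FALSE, TRUE, FALSE),
                    sample_rate_hz = 60)
  expect_error(interpolate_missing(one), "2 valid")
})

test_that("resampling preserves ramps exactly and sines closely", {
  t60 <- seq(0, 6, by = 1 / 60)
  ramp <- gaze_trace(2 * t60, -t60, sample_rate_hz = 60)
  up <- resample_to(ramp, 125)
  expect_equal(up$sample_rate_hz, 125)
  expect_lt(max(abs(up$horizontal_deg - 2 * gaze_times(up))), 1e-9)

  sine <- gaze_trace(sin(2 * pi * 0.5 * t60), sample_rate_hz = 60)
  up2 <- resample_to(sine, 125)
  expect_lt(max(abs(up2$horizontal_deg - sin(2 * pi * 0.5 * gaze_times(up2)))),
            0.01)

  same <- resample_to(ramp, 60)
  expect_lt(max(abs(same$horizontal_deg - ramp$horizontal_deg)), 1e-9)
  expect_error(resample_to(ramp, 0), "positive")
})

test_that("trial chains condition pursuit signals into [-1, 1]", {
  sch <- pursuit_schedule(amplitudes_deg = 10, frequencies_hz = 0.5,
                          axes = "horizontal", phases_rad = 0)
  sim <- simulate_session(sch, config = quiet_config())
  trials <- pursuit_trials(bandpass_recording(sim$recording), sim$camera,
                           sch, "horizontal")
  eog <- preprocess_eog_trial(differential(trials[[1]]$recording,
                                           montage_pair("L8", "R8")))
  expect_true(all(eog >= -1 & eog <= 1))
  expect_equal(max(eog), 1)
  expect_equal(min(eog), -1)

  # conditioned camera tracks the conditioned gold signal closely
  r <- abs(cor(trials[[1]]$gold, trials[[1]]$camera))
  expect_gt(r, 0.95)

  flat <- preprocess_eog_trial(rep(3, 750))
  expect_true(is_degenerate(flat))
})

test_that("conditioning stages preserve length and are deterministic", {
  set.seed(7)
  x <- rnorm(750)
  for (f in list(function(z) bandpass(z, 125),
                 detrend_linear,
                 function(z) mean_filter(z, 50),
                 normalize_unit)) {
    expect_length(f(x), length(x))
    expect_identical(f(x), f(x))
  }
})
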