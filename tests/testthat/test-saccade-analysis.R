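test_that("epoch extraction windows every outbound saccade", {
  sch <- saccade_schedule()
  sim <- simulate_recording(sch, config = quiet_config())
  rec <- bandpass_recording(sim$recording)
  ep <- extract_epochs(rec, sch)
  expect_length(ep, 24)
  expect_equal(attr(ep, "skipped"), 0L)
  expect_equal(nrow(ep[[1]]$window), 250)  # 2 s at 125 Hz

  with_returns <- extract_epochs(rec, sch, include_returns = TRUE)
  expect_length(with_returns, 48)
  ret <- with_returns[[2]]
  expect_identical(ret$kind, "saccade_return")
  expect_equal(ret$target_change_deg, -with_returns[[1]]$target_change_deg)

  # an event whose window leaves the recording is skipped, not errored
  short <- rec
  short$channels <- short$channels[seq_len(nrow(short$channels) - 900), ]
  ep2 <- extract_epochs(short, sch)
  expect_gt(attr(ep2, "skipped"), 0)
  expect_length(ep2, 24 - attr(ep2, "skipped"))
})

test_that("epoch windows start pre_onset_s before the stimulus jump", {
  sch <- saccade_schedule(angles_deg = 10, directions = "right")
  sim <- simulate_recording(sch, config = quiet_config())
  ep <- extract_epochs(sim$recording, sch, window_s = 2, pre_onset_s = 0.75)
  onset <- sch$events$start_s[sch$events$kind == "saccade_out"]
  i0 <- round((onset - 0.75) * 125) + 1
  expect_equal(ep[[1]]$window[, "hEOG"],
               sim$recording$channels[i0:(i0 + 249), "hEOG"])
})

test_that("the velocity labeler brackets a smoothed step and rejects noise", {
  step <- mean_filter(c(rep(0, 120), rep(-30, 130)), 9)
  lab <- label_saccade(step, "left")
  expect_true(lab$valid)
  expect_true(lab$start_idx <= 120 && lab$end_idx >= 121)
  expect_lt(abs(mean(step[seq_len(lab$start_idx - 1)]) - 0), 1)
  expect_lt(abs(mean(step[(lab$end_idx + 1):250]) + 30), 1)
  expect_equal(deflection(step, lab$start_idx, lab$end_idx, mode = "flank"),
               -30, tolerance = 1)

  set.seed(11)
  noise <- label_saccade(rnorm(250), "left")
  expect_false(noise$valid)
  flat <- label_saccade(rep(2, 250), "up")
  expect_false(flat$valid)
})

test_that("the labeler recovers injected onsets within 5 samples at SNR >= 10", {
  set.seed(12)
  for (snr in c(10, 20, 50)) {
    for (rep in 1:10) {
      onset <- sample(100:140, 1)
      clean <- mean_filter(c(rep(0, onset), rep(20, 250 - onset)), 9)
      # windows are band-passed before labeling; the noiseless label is
      # the reference the noisy label must reproduce
      ref <- label_saccade(bandpass(clean, 125), "right")
      noisy <- bandpass(clean + rnorm(250, sd = 20 / snr), 125)
      lab <- label_saccade(noisy, "right")
      expect_true(lab$valid)
      expect_lte(abs(lab$start_idx - ref$start_idx), 5)
      expect_lte(abs(lab$end_idx - ref$end_idx), 5)
      expect_true(ref$start_idx <= onset + 2 && ref$end_idx >= onset)
    }
  }
})

test_that("deflection is post-minus-pre and respects span requirements", {
  steps <- c(rep(0, 100), rep(-35, 100))
  expect_equal(deflection(steps, 96, 105, mode = "flank"), -35)
  expect_equal(deflection(steps, 81, 120, mode = "span"), -35)
  expect_equal(deflection(steps, 96, 105, mode = "window"), -35)
  expect_equal(deflection(rep(4, 200), 96, 105, mode = "flank"), 0)
  # span shorter than 20 samples is invalid
  expect_true(is.na(deflection(steps, 96, 105, mode = "span")))
  expect_true(is.na(deflection(steps, 5, 195, mode = "flank")))
  expect_true(is.na(deflection(steps, NA, NA, mode = "flank")))

  set.seed(13)
  d <- vapply(1:50, function(i) {
    noisy <- c(rep(0, 100), rep(10, 100)) + rnorm(200)
    deflection(noisy, 96, 105, mode = "flank")
  }, numeric(1))
  expect_lt(abs(mean(d) - 10), 0.5)
})

test_that("deflection records are antisymmetric in the montage order", {
  sch <- saccade_schedule(angles_deg = c(7.5, 15), directions = c("left", "right"))
  sim <- simulate_session(sch, config = quiet_config())
  ep <- extract_epochs(bandpass_recording(sim$recording), sch)
  fwd <- saccade_deflections(ep, list(montage_pair("L8", "R8")))
  rev <- saccade_deflections(ep, list(montage_pair("R8", "L8")))
  expect_equal(fwd[["L8-R8"]], -rev[["R8-L8"]], tolerance = 1e-9)
  expect_true(all(fwd$valid))
  expect_true(all(fwd$reliable))
})

test_that("vertical epochs are processed but flagged unreliable", {
  sch <- saccade_schedule(angles_deg = 15, directions = c("up", "down"))
  sim <- simulate_session(sch, config = quiet_config())
  ep <- extract_epochs(bandpass_recording(sim$recording), sch)
  rd <- saccade_deflections(ep, default_montages("vertical"))
  expect_true(all(!rd$reliable))
  expect_true(all(is.finite(rd$gold)))
})

test_that("average waveforms cancel constant baselines exactly", {
  sch <- saccade_schedule(angles_deg = 10, directions = "right")
  sim <- simulate_session(sch, config = quiet_config())
  ep <- extract_epochs(bandpass_recording(sim$recording), sch)
  pair <- montage_pair("L8", "R8")

  twice <- c(ep, ep)
  aw <- average_waveform(twice, pair)
  expect_equal(aw$n, 2)
  expect_true(all(aw$sd < 1e-12))

  shifted <- ep[[1]]
  shifted$window <- shifted$window + 17  # constant offset on every channel
  aw2 <- average_waveform(list(ep[[1]], shifted), pair)
  expect_true(all(aw2$sd < 1e-9))

  expect_error(average_waveform(list(), pair), "empty")
})

test_that("mean waveform step height grows with saccade amplitude", {
  sch <- saccade_schedule(directions = "right")
  sim <- simulate_session(sch, config = quiet_config())
  ep <- extract_epochs(bandpass_recording(sim$recording), sch)
  pair <- montage_pair("R8", "L8")  # positive gain for rightward gaze
  heights <- vapply(ep, function(e) {
    aw <- average_waveform(list(e), pair)
    max(aw$mean) - min(aw$mean)
  }, numeric(1))
  amp <- vapply(ep, function(e) e$amplitude_deg, numeric(1))
  ord <- order(amp)
  expect_true(all(diff(heights[ord]) > 0))
})

test_that("epochs resample to a common length preserving shape", {
  sch <- saccade_schedule(angles_deg = 10, directions = "right")
  sim <- simulate_session(sch, config = quiet_config())
  ep <- extract_epochs(bandpass_recording(sim$recording), sch)

  same <- interpolate_to_common_length(ep, nrow(ep[[1]]$window))
  expect_equal(same[[1]]$window, ep[[1]]$window)

  ramp_ep <- ep[[1]]
  ramp_ep$window <- matrix(seq(0, 1, length.out = 250), ncol = 1,
                           dimnames = list(NULL, "hEOG"))
  out <- interpolate_to_common_length(list(ramp_ep), 125)[[1]]
  expect_equal(out$window[, 1], seq(0, 1, length.out = 125), tolerance = 1e-12)

  step_ep <- ramp_ep
  step_ep$window <- matrix(c(rep(0, 100), rep(1, 150)), ncol = 1,
                           dimnames = list(NULL, "hEOG"))
  out2 <- interpolate_to_common_length(list(step_ep), 500)[[1]]
  jump_rel_in <- 100 / 250
  jump_rel_out <- max(which(out2$window[, 1] < 0.5)) / 500
  expect_lt(abs(jump_rel_out - jump_rel_in), 1 / 250)

  expect_error(interpolate_to_common_length(ep, 19), "at least 20")
})

test_that("deflection-amplitude correlation matches its closed forms", {
  ear <- c(-35, -20, -8, 9, 16, 41)
  expect_equal(deflection_amplitude_correlation(ear, 2 * ear)$statistic, 1,
               tolerance = 1e-12)
  expect_equal(deflection_amplitude_correlation(ear, -3 * ear)$statistic, -1,
               tolerance = 1e-12)

  # engineered r = 0.79 at n = 6 reproduces the two-sided p of ~0.061
  x <- scale(1:6)[, 1]
  x <- x / sqrt(sum(x^2))
  e <- c(1, -2, 1, 1, -2, 1)
  e <- resid(lm(e ~ x))
  e <- e / sqrt(sum(e^2))
  y <- 0.79 * x + sqrt(1 - 0.79^2) * e
  ct <- deflection_amplitude_correlation(x, y)
  expect_equal(ct$statistic, 0.79, tolerance = 1e-9)
  expect_lt(abs(ct$p_value - 0.061), 2e-3)
  expect_equal(ct$n, 6L)

  expect_error(deflection_amplitude_correlation(1:2, 1:2), "at least 3")
  expect_error(deflection_amplitude_correlation(1:5, 1:4), "paired")
})
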