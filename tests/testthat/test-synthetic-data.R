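test_that("dipole potential has the mid-sagittal and mirror symmetries", {
  eyes <- default_eye_centers()
  # electrode on the mid-sagittal plane, equidistant from both eyes
  mid <- c(0, 0.02, 0.05)
  left <- c(-0.06, 0.02, 0.05)
  right <- c(0.06, 0.02, 0.05)
  expect_equal(dipole_potential(0, 0, left, eyes) -
                 dipole_potential(0, 0, right, eyes), 0, tolerance = 1e-12)
  expect_equal(dipole_potential(0, 0, mid, eyes),
               dipole_potential(0, 0, mid, eyes))

  # mirrored gaze with mirrored electrodes negates the differential
  for (th in c(5, 10, 15)) {
    d_pos <- dipole_potential(th, 0, left, eyes) -
      dipole_potential(th, 0, right, eyes)
    d_neg <- dipole_potential(-th, 0, left, eyes) -
      dipole_potential(-th, 0, right, eyes)
    expect_equal(d_pos, -d_neg, tolerance = 1e-12)
  }

  expect_error(dipole_potential(0, 0, eyes[1, ] + c(1e-4, 0, 0), eyes),
               "1 mm")
})

test_that("differential potential is nearly linear over the +/-15 deg range", {
  lay <- default_electrode_layout()
  th <- seq(-15, 15, by = 2.5)
  d <- dipole_potential(th, 0, electrode_position(lay, "L8")) -
    dipole_potential(th, 0, electrode_position(lay, "R8"))
  fit <- summary(stats::lm(d ~ th))
  expect_gt(fit$r.squared, 0.99)
})

test_that("simulate_recording is deterministic and seed-sensitive", {
  sch <- saccade_schedule(angles_deg = c(5, 15), directions = "right")
  a <- simulate_recording(sch, config = quiet_config())
  b <- simulate_recording(sch, config = quiet_config())
  expect_identical(a$recording$channels, b$recording$channels)

  noisy1 <- simulate_recording(sch, config = synth_config(rng_seed = 10))
  noisy1b <- simulate_recording(sch, config = synth_config(rng_seed = 10))
  noisy2 <- simulate_recording(sch, config = synth_config(rng_seed = 11))
  expect_identical(noisy1$recording$channels, noisy1b$recording$channels)
  expect_false(identical(noisy1$recording$channels, noisy2$recording$channels))
})

test_that("channel potentials scale linearly with the dipole moment", {
  sch <- saccade_schedule(angles_deg = 15, directions = "right")
  base <- simulate_recording(sch, config = quiet_config())
  doubled <- simulate_recording(
    sch, config = quiet_config(dipole_moment_uVm2 = 2 * 0.21))
  h1 <- get_channel(base$recording, "hEOG")
  h2 <- get_channel(doubled$recording, "hEOG")
  expect_equal(h2, 2 * h1, tolerance = 1e-9)
})

test_that("clock skew shifts the electrical channels against the truth", {
  sch <- saccade_schedule(angles_deg = 15, directions = "right")
  plain <- simulate_recording(sch, config = quiet_config())
  skewed <- simulate_recording(sch, config = quiet_config(clock_skew_samples = 5L))
  x <- get_channel(plain$recording, "hEOG")
  y <- get_channel(skewed$recording, "hEOG")
  n <- length(x)
  expect_equal(y[6:n], x[1:(n - 5)], tolerance = 1e-12)
})

test_that("camera model resamples, drops out and delays as configured", {
  sch <- pursuit_schedule(amplitudes_deg = 10, frequencies_hz = 0.5,
                          axes = "horizontal", seed = 2)
  truth <- simulate_recording(sch, config = quiet_config())$truth
  cam <- simulate_camera(truth, quiet_config())
  expect_equal(cam$sample_rate_hz, 60)
  t_cam <- gaze_times(cam)
  ref <- approx(gaze_times(truth), truth$horizontal_deg, xout = t_cam)$y
  expect_lt(max(abs(cam$horizontal_deg - ref)), 0.01)

  # dropout count within 3 sigma of the binomial expectation
  long <- pursuit_schedule(axes = "horizontal", seed = 3)
  truth2 <- simulate_recording(long, config = quiet_config())$truth
  cam2 <- simulate_camera(truth2, quiet_config(camera_dropout_prob = 0.1,
                                               seed = 99L))
  n <- length(cam2$valid)
  invalid <- sum(!cam2$valid)
  expect_lt(abs(invalid - 0.1 * n), 3 * sqrt(n * 0.1 * 0.9))
  expect_true(all(is.na(cam2$horizontal_deg[!cam2$valid])))

  expect_error(synth_config(camera_dropout_prob = 1), "camera_dropout_prob")
  expect_error(synth_config(camera_latency_s = 0.7), "camera_latency_s")
})

test_that("the cross-ear pair with the largest gain gives the largest signal", {
  lay <- default_electrode_layout()
  cands <- default_montages("horizontal")
  # expected winner from the dipole model directly
  gain <- vapply(cands, function(p) {
    d <- function(th) {
      dipole_potential(th, 0, electrode_position(lay, p$channel_a)) -
        dipole_potential(th, 0, electrode_position(lay, p$channel_b))
    }
    abs(d(15) - d(0))
  }, numeric(1))
  cross_ear <- vapply(cands, function(p) {
    substr(p$channel_a, 1, 1) != substr(p$channel_b, 1, 1)
  }, logical(1))
  expected <- montage_label(cands[[which.max(gain * cross_ear)]])

  sch <- pursuit_schedule(amplitudes_deg = c(5, 15), frequencies_hz = 0.5,
                          axes = "horizontal", seed = 8)
  sim <- simulate_recording(sch, config = quiet_config())
  amp <- vapply(cands, function(p) sd(differential(sim$recording, p)),
                numeric(1))
  expect_identical(montage_label(cands[[which.max(amp)]]), expected)
  expect_identical(expected, "L8-R8")
})

test_that("noiseless saccade steps are linear in signed amplitude", {
  sch <- saccade_schedule(directions = c("left", "right"))
  sim <- simulate_recording(sch, config = quiet_config())
  pair <- montage_pair("L8", "R8")
  d <- differential(sim$recording, pair)
  ev <- sch$events[sch$events$kind == "saccade_out", ]
  step <- vapply(seq_len(nrow(ev)), function(i) {
    i_pre <- round((ev$start_s[i] - 0.2) * 125)
    i_post <- round((ev$start_s[i] + 1.5) * 125)
    d[i_post] - d[i_pre]
  }, numeric(1))
  signed <- ifelse(ev$direction == "right", 1, -1) * ev$amplitude_deg
  expect_gt(abs(cor(step, signed)), 0.999)
})
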