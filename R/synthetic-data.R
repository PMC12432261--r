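# Forward simulation: corneo-retinal dipole projection of a gaze trajectory
# onto the electrode layout, plus sensor noise, drift, mains interference,
# and a camera eye-tracker model with latency, noise and dropout.

#' Simulation configuration
#'
#' Parameters of the synthetic recording generator. The defaults reproduce
#' desk-scale laboratory conditions: a dipole moment giving a ~40 uV
#' noiseless cross-ear step for a 15-degree saccade (and ~10 uV/degree for
#' gold-standard horizontal EOG), a few microvolts of sensor noise and
#' drift, mains interference at 50 Hz (removed by the 15 Hz low-pass edge),
#' and a 60 Hz camera with latency, angular noise and sample dropout.
#'
#' @param dipole_moment_uVm2 corneo-retinal dipole moment scale per eye,
#'   in uV m^2 (potential = moment * projection / distance^2).
#' @param eye_centers 2 x 3 matrix of eye centers (meters, head frame).
#' @param noise_white_uV white sensor noise SD per channel, uV.
#' @param drift_random_walk_uV_per_sqrt_s baseline drift random-walk scale.
#' @param line_50hz_uV mains interference amplitude, uV.
#' @param camera_noise_deg camera angular noise SD, degrees.
#' @param camera_dropout_prob per-sample probability a camera sample is
#'   missing; must be `< 1`.
#' @param camera_latency_s camera reporting latency, seconds, in `[0, 0.5]`.
#' @param clock_skew_samples integer shift of the EOG device clock relative
#'   to the stimulus/camera clock, in samples.
#' @param saccade_latency_s reaction latency used when rendering schedules.
#' @param rng_seed integer seed; identical configs give identical output.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(dipole_moment_uVm2 = 0.21,
                         eye_centers = default_eye_centers(),
                         noise_white_uV = 2,
                         drift_random_walk_uV_per_sqrt_s = 3,
                         line_50hz_uV = 5,
                         camera_noise_deg = 0.3,
                         camera_dropout_prob = 0.02,
                         camera_latency_s = 0.1,
                         clock_skew_samples = 0L,
                         saccade_latency_s = 0.2,
                         rng_seed = 1L) {
  cfg <- list(dipole_moment_uVm2 = dipole_moment_uVm2,
              eye_centers = eye_centers,
              noise_white_uV = noise_white_uV,
              drift_random_walk_uV_per_sqrt_s = drift_random_walk_uV_per_sqrt_s,
              line_50hz_uV = line_50hz_uV,
              camera_noise_deg = camera_noise_deg,
              camera_dropout_prob = camera_dropout_prob,
              camera_latency_s = camera_latency_s,
              clock_skew_samples = as.integer(clock_skew_samples),
              saccade_latency_s = saccade_latency_s,
              rng_seed = as.integer(rng_seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  bad <- character()
  if (!isTRUE(cfg$dipole_moment_uVm2 > 0)) bad <- c(bad, "dipole_moment_uVm2")
  if (!is.matrix(cfg$eye_centers) || !all(dim(cfg$eye_centers) == c(2, 3))) {
    bad <- c(bad, "eye_centers")
  }
  for (key in c("noise_white_uV", "drift_random_walk_uV_per_sqrt_s",
                "line_50hz_uV", "camera_noise_deg")) {
    if (!isTRUE(cfg[[key]] >= 0)) bad <- c(bad, key)
  }
  if (!isTRUE(cfg$camera_dropout_prob >= 0 && cfg$camera_dropout_prob < 1)) {
    bad <- c(bad, "camera_dropout_prob")
  }
  if (!isTRUE(cfg$camera_latency_s >= 0 && cfg$camera_latency_s <= 0.5)) {
    bad <- c(bad, "camera_latency_s")
  }
  if (!isTRUE(cfg$saccade_latency_s >= 0)) bad <- c(bad, "saccade_latency_s")
  if (length(bad) > 0) {
    stop("invalid synth_config field(s): ", paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

# unit gaze vector in the head frame (x right, y anterior, z superior)
gaze_unit_vector <- function(h_deg, v_deg) {
  h <- h_deg * pi / 180
  v <- v_deg * pi / 180
  cbind(sin(h) * cos(v), cos(h) * cos(v), sin(v))
}

#' Corneo-retinal dipole potential at an electrode
#'
#' The standing potential of each eye is modelled as a point dipole at the
#' eye center, oriented along the gaze direction (cornea positive). The
#' potential at an electrode in a homogeneous medium is
#' `V = m * sum_eyes (g . r) / |r|^3` with `g` the unit gaze vector and `r`
#' the eye-to-electrode vector. Smooth in the gaze angles and, over the
#' +/- 15 degree range used here, very close to linear.
#'
#' @param gaze_h_deg,gaze_v_deg gaze angles in degrees (vectors of equal
#'   length are accepted).
#' @param electrode_position length-3 position in meters.
#' @param eye_centers 2 x 3 matrix of eye centers in meters.
#' @param moment_scale dipole moment in uV m^2.
#' @return potential in uV (vectorized over the gaze series).
#' @export
dipole_potential <- function(gaze_h_deg, gaze_v_deg, electrode_position,
                             eye_centers = default_eye_centers(),
                             moment_scale = 1) {
  g <- gaze_unit_vector(gaze_h_deg, gaze_v_deg)
  v <- 0
  for (k in 1:2) {
    r <- electrode_position - eye_centers[k, ]
    dist <- sqrt(sum(r^2))
    if (dist < 1e-3) stop("electrode within 1 mm of an eye center")
    v <- v + moment_scale * as.numeric(g %*% r) / dist^3
  }
  v
}

# matrix of potentials (samples x electrodes) for a gaze trace
project_gaze <- function(truth, layout, config) {
  vapply(layout$label, function(lab) {
    dipole_potential(truth$horizontal_deg, truth$vertical_deg,
                     electrode_position(layout, lab),
                     config$eye_centers, config$dipole_moment_uVm2)
  }, numeric(length(truth$horizontal_deg)))
}

# delay a series by an integer number of samples, padding with the edge value
shift_series <- function(x, k) {
  n <- length(x)
  if (k == 0) return(x)
  if (abs(k) >= n) stop("shift exceeds series length")
  if (k > 0) c(rep(x[1], k), x[seq_len(n - k)]) else c(x[(1 - k):n], rep(x[n], -k))
}

#' Simulate a periauricular + periorbital EOG recording
#'
#' Renders the schedule's ideal gaze trajectory, projects it through the
#' corneo-retinal dipole model onto every electrode of the layout, and
#' composes the measured channels: periauricular channels referenced against
#' the reference electrode, and bipolar gold-standard channels `hEOG`
#' (outer canthi) and `vEOG` (above/below the left eye). Each channel then
#' receives seeded white noise, random-walk baseline drift and a 50 Hz
#' mains component. Identical configurations give byte-identical output.
#'
#' @param schedule a `stimulus_schedule`.
#' @param layout an [electrode_layout()]; needs at least 2 measurement
#'   channels plus the periorbital set.
#' @param config a [synth_config()].
#' @param sample_rate_hz EOG sampling rate (default 125).
#' @return list with `recording` (an [eog_recording()]) and `truth`
#'   (the ideal [gaze_trace()] at the EOG rate).
#' @export
simulate_recording <- function(schedule, layout = default_electrode_layout(),
                               config = synth_config(), sample_rate_hz = 125) {
  validate_synth_config(config)
  meas <- layout$label[layout$role == "measurement" & layout$side != "periorbital"]
  if (length(meas) < 2) stop("layout needs at least 2 measurement channels")
  truth <- schedule_to_gaze(schedule, sample_rate_hz,
                            latency_s = config$saccade_latency_s)
  pot <- project_gaze(truth, layout, config)
  if (config$clock_skew_samples != 0) {
    pot <- apply(pot, 2, shift_series, k = config$clock_skew_samples)
  }
  ref <- layout$label[layout$role == "reference"]
  channels <- pot[, meas, drop = FALSE] - pot[, ref]
  gold <- cbind(
    hEOG = pot[, "hEOG_right"] - pot[, "hEOG_left"],
    vEOG = pot[, "vEOG_upper"] - pot[, "vEOG_lower"]
  )
  channels <- cbind(channels, gold)
  n <- nrow(channels)
  fs <- sample_rate_hz
  channels <- withr::with_seed(config$rng_seed, {
    t <- (seq_len(n) - 1) / fs
    for (j in seq_len(ncol(channels))) {
      white <- if (config$noise_white_uV > 0) {
        rnorm(n, sd = config$noise_white_uV)
      } else 0
      drift <- if (config$drift_random_walk_uV_per_sqrt_s > 0) {
        cumsum(rnorm(n, sd = config$drift_random_walk_uV_per_sqrt_s / sqrt(fs)))
      } else 0
      line <- if (config$line_50hz_uV > 0) {
        config$line_50hz_uV * sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
      } else 0
      channels[, j] <- channels[, j] + white + drift + line
    }
    channels
  })
  list(recording = eog_recording(channels, sample_rate_hz = fs),
       truth = truth)
}

#' Simulate the camera eye tracker
#'
#' Resamples the true gaze to the camera rate, delays it by the camera
#' latency, adds Gaussian angular noise, and knocks out samples with the
#' dropout probability (flagged invalid, values set to `NA`).
#'
#' @param truth a [gaze_trace()] (typically the simulator's 125 Hz truth).
#' @param config a [synth_config()].
#' @param camera_rate_hz output rate in Hz (default 60).
#' @return a [gaze_trace()] at the camera rate.
#' @export
simulate_camera <- function(truth, config = synth_config(), camera_rate_hz = 60) {
  validate_synth_config(config)
  if (config$camera_dropout_prob >= 1) stop("camera_dropout_prob must be < 1")
  t_truth <- gaze_times(truth)
  t_cam <- seq(t_truth[1], t_truth[length(t_truth)], by = 1 / camera_rate_hz)
  sample_axis <- function(x) {
    approx(t_truth, x, xout = t_cam - config$camera_latency_s, rule = 2)$y
  }
  h <- sample_axis(truth$horizontal_deg)
  v <- sample_axis(truth$vertical_deg)
  withr::with_seed(config$rng_seed + 1000003L, {
    if (config$camera_noise_deg > 0) {
      h <- h + rnorm(length(h), sd = config$camera_noise_deg)
      v <- v + rnorm(length(v), sd = config$camera_noise_deg)
    }
    valid <- runif(length(h)) >= config$camera_dropout_prob
    h[!valid] <- NA_real_
    v[!valid] <- NA_real_
    gaze_trace(h, v, valid, sample_rate_hz = camera_rate_hz,
               start_time_s = t_cam[1])
  })
}

#' Simulate one participant session
#'
#' Convenience wrapper producing the recording, the truth trace and the
#' camera trace for a schedule in one call.
#'
#' @inheritParams simulate_recording
#' @return list with `recording`, `truth`, `camera` and `schedule`.
#' @export
simulate_session <- function(schedule, layout = default_electrode_layout(),
                             config = synth_config()) {
  sim <- simulate_recording(schedule, layout, config)
  cam <- simulate_camera(sim$truth, config)
  list(recording = sim$recording, truth = sim$truth, camera = cam,
       schedule = schedule)
}
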