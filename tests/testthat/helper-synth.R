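# shared fixtures: noiseless / calibrated-noise simulator configs and a
# combiner for multi-participant trial lists

quiet_config <- function(seed = 1L, latency = 0, ...) {
  args <- utils::modifyList(
    list(noise_white_uV = 0, drift_random_walk_uV_per_sqrt_s = 0,
         line_50hz_uV = 0, camera_noise_deg = 0, camera_dropout_prob = 0,
         camera_latency_s = latency, rng_seed = seed),
    list(...))
  do.call(synth_config, args)
}

# white-noise sigma giving the requested SNR for a montage's noiseless
# differential signal under a schedule
sigma_for_snr <- function(schedule, pair, snr,
                          layout = default_electrode_layout()) {
  sim <- simulate_recording(schedule, layout, quiet_config())
  sd(differential(sim$recording, pair)) / snr
}

# concatenate pursuit_trials lists from several sessions
combine_trials <- function(...) {
  lists <- list(...)
  orientation <- attr(lists[[1]], "orientation")
  out <- do.call(c, lapply(lists, unclass))
  structure(out, orientation = orientation, class = "pursuit_trials")
}

# simulate one pursuit session and cut trials
pursuit_session_trials <- function(seed, config, orientation = "horizontal",
                                   axes = orientation, ...) {
  sch <- pursuit_schedule(axes = axes, seed = seed, ...)
  sim <- simulate_session(sch, config = config)
  pursuit_trials(bandpass_recording(sim$recording), sim$camera, sch, orientation)
}
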