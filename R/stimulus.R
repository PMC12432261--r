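# Stimulus schedules: sinusoidal 1-D smooth pursuits and step saccades on a
# desktop monitor, plus the ideal gaze trajectories they imply.

#' Screen geometry
#'
#' Physical description of the stimulus monitor: a 23-inch 16:9 panel at
#' 1920 x 1080 viewed from 0.5 m by default.
#'
#' @param diagonal_m physical diagonal in meters (default 0.5842 = 23 in).
#' @param resolution_px integer pair, horizontal x vertical pixels.
#' @param viewing_distance_m eye-to-screen distance in meters.
#' @return a `screen_geometry` list with derived `width_m` and `height_m`.
#' @export
screen_geometry <- function(diagonal_m = 0.5842, resolution_px = c(1920, 1080),
                            viewing_distance_m = 0.5) {
  stopifnot(diagonal_m > 0, viewing_distance_m > 0, all(resolution_px > 0))
  aspect <- resolution_px[1] / resolution_px[2]
  height <- diagonal_m / sqrt(1 + aspect^2)
  structure(
    list(diagonal_m = diagonal_m, resolution_px = as.integer(resolution_px),
         viewing_distance_m = viewing_distance_m,
         width_m = height * aspect, height_m = height),
    class = "screen_geometry"
  )
}

#' Visual angle to on-screen offset
#'
#' Converts a visual angle into the lateral offset on the screen plane,
#' `offset = distance * tan(angle)`, in millimeters.
#'
#' @param angle_deg visual angle in degrees; must satisfy `|angle| < 90`.
#' @param geometry a [screen_geometry()].
#' @return offset in millimeters.
#' @export
deg_to_screen_mm <- function(angle_deg, geometry = screen_geometry()) {
  if (any(abs(angle_deg) >= 90)) stop("angle must satisfy |angle| < 90 degrees")
  1000 * geometry$viewing_distance_m * tan(angle_deg * pi / 180)
}

#' @rdname deg_to_screen_mm
#' @param px length in pixels (horizontal pitch).
#' @export
px_to_mm <- function(px, geometry = screen_geometry()) {
  px * 1000 * geometry$width_m / geometry$resolution_px[1]
}

#' Sinusoidal smooth-pursuit trajectory
#'
#' The pursuit target oscillates on one axis in simple harmonic motion:
#' `theta(t) = A sin(2 pi f t + phi)`; the other axis stays at zero. Opening
#' angle `A` is the maximum deviation from screen center along the axis.
#'
#' @param amplitude_deg opening angle A in degrees (> 0).
#' @param frequency_hz oscillation frequency in Hz.
#' @param phase_rad starting phase in radians.
#' @param duration_s trial duration in seconds (default 6).
#' @param axis `"horizontal"` or `"vertical"`.
#' @param sample_rate_hz output sampling rate in Hz.
#' @return a [gaze_trace()] of `round(duration_s * sample_rate_hz)` samples.
#' @export
pursuit_trajectory <- function(amplitude_deg, frequency_hz, phase_rad = 0,
                               duration_s = 6, axis = c("horizontal", "vertical"),
                               sample_rate_hz = 125) {
  axis <- match.arg(axis)
  stopifnot(amplitude_deg > 0, frequency_hz > 0, duration_s > 0)
  if (sample_rate_hz <= 0) stop("`sample_rate_hz` must be positive")
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  theta <- amplitude_deg * sin(2 * pi * frequency_hz * t + phase_rad)
  zero <- numeric(n)
  if (axis == "horizontal") {
    gaze_trace(theta, zero, sample_rate_hz = sample_rate_hz)
  } else {
    gaze_trace(zero, theta, sample_rate_hz = sample_rate_hz)
  }
}

new_schedule <- function(events, geometry, cycle_index = 1L, rng_seed = NA_integer_) {
  events <- events[order(events$start_s), ]
  rownames(events) <- NULL
  ends <- events$start_s + events$duration_s
  if (nrow(events) > 1 &&
      any(events$start_s[-1] < ends[-nrow(events)] - 1e-9)) {
    stop("schedule events overlap")
  }
  if (events$kind[nrow(events)] != "rest") stop("schedule must end with a rest event")
  structure(
    list(events = events, geometry = geometry,
         cycle_index = as.integer(cycle_index), rng_seed = rng_seed),
    class = "stimulus_schedule"
  )
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule> %d events, %.1f s total\n",
              nrow(x$events), schedule_duration(x)))
  print(table(x$events$kind))
  invisible(x)
}

#' @rdname saccade_schedule
#' @param schedule a `stimulus_schedule`.
#' @export
schedule_duration <- function(schedule) {
  sum(schedule$events$duration_s)
}

empty_events <- function() {
  data.frame(kind = character(), axis = character(), direction = character(),
             amplitude_deg = numeric(), frequency_hz = numeric(),
             phase_rad = numeric(), start_s = numeric(), duration_s = numeric(),
             cycle = integer())
}

event_row <- function(kind, start_s, duration_s, axis = NA_character_,
                      direction = NA_character_, amplitude_deg = NA_real_,
                      frequency_hz = NA_real_, phase_rad = NA_real_,
                      cycle = NA_integer_) {
  data.frame(kind = kind, axis = axis, direction = direction,
             amplitude_deg = amplitude_deg, frequency_hz = frequency_hz,
             phase_rad = phase_rad, start_s = start_s, duration_s = duration_s,
             cycle = cycle)
}

#' Saccade stimulus schedule
#'
#' A fixation point jumps from the screen center to `angles_deg` in each of
#' the cardinal `directions` (one `saccade_out` event per jump, held for
#' `fixation_s`), then returns to center (`saccade_return`, held for
#' `rest_s`), for `cycles` repetitions. The default grid -- six angles from
#' 2.5 to 15 degrees in 2.5-degree steps, four directions -- emits 24
#' out-events per cycle.
#'
#' @param angles_deg positive ascending saccade amplitudes in degrees.
#' @param directions subset of `"left"`, `"right"`, `"up"`, `"down"`.
#' @param fixation_s outward fixation duration in seconds (default 2).
#' @param rest_s center fixation duration in seconds (default 2).
#' @param cycles number of repetitions of the full grid.
#' @param geometry a [screen_geometry()].
#' @return a `stimulus_schedule`.
#' @export
saccade_schedule <- function(angles_deg = seq(2.5, 15, by = 2.5),
                             directions = c("left", "right", "up", "down"),
                             fixation_s = 2, rest_s = 2, cycles = 1,
                             geometry = screen_geometry()) {
  if (length(angles_deg) == 0) stop("empty angle list")
  if (any(angles_deg <= 0) || is.unsorted(angles_deg, strictly = TRUE)) {
    stop("angles must be positive and ascending")
  }
  if (!all(directions %in% c("left", "right", "up", "down"))) {
    stop("unknown direction")
  }
  stopifnot(fixation_s > 0, rest_s > 0, cycles >= 1)
  rows <- list(event_row("rest", 0, rest_s))
  t <- rest_s
  for (cy in seq_len(cycles)) {
    for (d in directions) {
      ax <- if (d %in% c("left", "right")) "horizontal" else "vertical"
      for (a in angles_deg) {
        rows[[length(rows) + 1]] <- event_row("saccade_out", t, fixation_s,
                                              axis = ax, direction = d,
                                              amplitude_deg = a, cycle = cy)
        t <- t + fixation_s
        rows[[length(rows) + 1]] <- event_row("saccade_return", t, rest_s,
                                              axis = ax, direction = d,
                                              amplitude_deg = a, cycle = cy)
        t <- t + rest_s
      }
    }
  }
  rows[[length(rows) + 1]] <- event_row("rest", t, rest_s)
  new_schedule(do.call(rbind, rows), geometry)
}

#' Smooth-pursuit stimulus schedule
#'
#' One 6-second sinusoidal pursuit trial per combination of opening angle,
#' frequency and axis, separated by center rests. Each trial's starting
#' phase is drawn uniformly from a seeded generator and recorded in the
#' event, so schedules are reproducible.
#'
#' @param amplitudes_deg opening angles in degrees.
#' @param frequencies_hz pursuit frequencies in Hz (defaults 0.33, 0.5, 1).
#' @param axes `"horizontal"`, `"vertical"` or both.
#' @param duration_s trial duration in seconds (default 6).
#' @param rest_s rest between trials in seconds.
#' @param cycles repetitions of the full grid.
#' @param seed RNG seed for the starting phases.
#' @param phases_rad optional fixed starting phase(s), recycled across
#'   trials; overrides the seeded random draw.
#' @param geometry a [screen_geometry()].
#' @return a `stimulus_schedule`.
#' @export
pursuit_schedule <- function(amplitudes_deg = seq(2.5, 15, by = 2.5),
                             frequencies_hz = c(0.33, 0.5, 1),
                             axes = c("horizontal", "vertical"),
                             duration_s = 6, rest_s = 2, cycles = 1,
                             seed = 1L, phases_rad = NULL,
                             geometry = screen_geometry()) {
  if (length(amplitudes_deg) == 0) stop("empty amplitude list")
  stopifnot(all(amplitudes_deg > 0), all(frequencies_hz > 0),
            duration_s > 0, rest_s > 0, cycles >= 1)
  if (!all(axes %in% c("horizontal", "vertical"))) stop("unknown axis")
  grid <- expand.grid(amplitude = amplitudes_deg, frequency = frequencies_hz,
                      axis = axes, cycle = seq_len(cycles),
                      stringsAsFactors = FALSE)
  phases <- if (is.null(phases_rad)) {
    withr::with_seed(seed, runif(nrow(grid), 0, 2 * pi))
  } else {
    rep_len(phases_rad, nrow(grid))
  }
  rows <- list(event_row("rest", 0, rest_s))
  t <- rest_s
  for (i in seq_len(nrow(grid))) {
    rows[[length(rows) + 1]] <- event_row("pursuit", t, duration_s,
                                          axis = grid$axis[i],
                                          amplitude_deg = grid$amplitude[i],
                                          frequency_hz = grid$frequency[i],
                                          phase_rad = phases[i],
                                          cycle = grid$cycle[i])
    t <- t + duration_s
    rows[[length(rows) + 1]] <- event_row("rest", t, rest_s)
    t <- t + rest_s
  }
  new_schedule(do.call(rbind, rows), geometry, rng_seed = seed)
}

# amplitude with sign convention right/up positive, left/down negative
signed_amplitude <- function(direction, amplitude_deg) {
  sign <- ifelse(direction %in% c("right", "up"), 1, -1)
  sign * amplitude_deg
}

# raised-cosine step from 0 to 1 over [t0, t0 + dur]
smooth_step <- function(t, t0, dur) {
  if (dur <= 0) return(as.numeric(t >= t0))
  s <- pmin(pmax((t - t0) / dur, 0), 1)
  0.5 - 0.5 * cos(pi * s)
}

# main-sequence saccade duration in seconds for a given amplitude
saccade_duration_s <- function(amplitude_deg) {
  0.021 + 0.0022 * abs(amplitude_deg)
}

#' Ideal gaze trajectory implied by a schedule
#'
#' Renders a schedule as the gaze of an ideal observer: the sinusoid during
#' pursuit trials, a step with a configurable reaction latency (and a brief
#' main-sequence-scaled ballistic transition) at saccade events, and 0
#' degrees during rests.
#'
#' @param schedule a `stimulus_schedule`.
#' @param sample_rate_hz output rate in Hz (default 125).
#' @param latency_s saccadic reaction latency in seconds added after each
#'   target jump (default 0.2).
#' @param ballistic if `TRUE` (default) saccades follow a raised-cosine
#'   transition of main-sequence duration; if `FALSE` they are ideal steps.
#' @return a [gaze_trace()] covering the schedule's full duration.
#' @export
schedule_to_gaze <- function(schedule, sample_rate_hz = 125, latency_s = 0.2,
                             ballistic = TRUE) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  if (sample_rate_hz <= 0) stop("`sample_rate_hz` must be positive")
  total <- schedule_duration(schedule)
  n <- round(total * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  h <- numeric(n)
  v <- numeric(n)
  ev <- schedule$events
  pos <- c(horizontal = 0, vertical = 0)
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (e$kind == "pursuit") {
      inwin <- t >= e$start_s & t < e$start_s + e$duration_s
      theta <- e$amplitude_deg *
        sin(2 * pi * e$frequency_hz * (t[inwin] - e$start_s) + e$phase_rad)
      if (e$axis == "horizontal") h[inwin] <- theta else v[inwin] <- theta
    } else if (e$kind %in% c("saccade_out", "saccade_return")) {
      target <- if (e$kind == "saccade_out") {
        signed_amplitude(e$direction, e$amplitude_deg)
      } else 0
      from <- pos[[e$axis]]
      dur <- if (ballistic) saccade_duration_s(target - from) else 0
      step <- smooth_step(t, e$start_s + latency_s, dur)
      if (e$axis == "horizontal") {
        h <- h + (target - from) * step
      } else {
        v <- v + (target - from) * step
      }
      pos[[e$axis]] <- target
    }
  }
  gaze_trace(h, v, sample_rate_hz = sample_rate_hz)
}

#' Read / write a stimulus schedule as JSON
#'
#' @param schedule a `stimulus_schedule`.
#' @param path file path.
#' @export
write_schedule_json <- function(schedule, path) {
  obj <- list(
    geometry = unclass(schedule$geometry),
    cycle_index = schedule$cycle_index,
    rng_seed = schedule$rng_seed,
    events = schedule$events
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geo <- screen_geometry(obj$geometry$diagonal_m,
                         obj$geometry$resolution_px,
                         obj$geometry$viewing_distance_m)
  ev <- as.data.frame(obj$events)
  for (col in c("axis", "direction")) ev[[col]] <- as.character(ev[[col]])
  seed <- if (is.null(obj$rng_seed)) NA_integer_ else obj$rng_seed
  new_schedule(ev, geo, cycle_index = obj$cycle_index %||% 1L, rng_seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
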