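# Core data model: multichannel potential recordings, gaze traces, electrode
# layouts, and plain-CSV I/O. Conventions, fixed package-wide: time in
# seconds, potentials in microvolts, angles in degrees (right/up positive),
# windows half-open in time [start, end).

#' Multichannel EOG recording
#'
#' A uniformly sampled set of potential series in microvolts, one per
#' labelled channel.
#'
#' @param channels named list of equal-length numeric vectors, or a numeric
#'   matrix with one column per channel (column names are the labels), in uV.
#' @param sample_rate_hz sampling rate in Hz (default 125).
#' @param start_time_s time of the first sample in seconds.
#' @return an object of class `eog_recording` with elements `channels`
#'   (matrix, one column per channel), `sample_rate_hz`, `start_time_s`.
#' @examples
#' rec <- eog_recording(list(L8 = sin(1:250 / 10), R8 = cos(1:250 / 10)))
#' channel_labels(rec)
#' @export
eog_recording <- function(channels, sample_rate_hz = 125, start_time_s = 0) {
  if (is.list(channels)) {
    lens <- lengths(channels)
    if (length(unique(lens)) > 1) stop("all channel series must have equal length")
    channels <- do.call(cbind, channels)
  }
  channels <- as.matrix(channels)
  if (is.null(colnames(channels))) stop("channels must be labelled")
  if (anyDuplicated(colnames(channels))) stop("duplicated channel labels")
  if (!all(is.finite(channels))) stop("all channel values must be finite")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be positive")
  }
  structure(
    list(channels = channels, sample_rate_hz = sample_rate_hz,
         start_time_s = start_time_s),
    class = "eog_recording"
  )
}

#' @export
print.eog_recording <- function(x, ...) {
  cat(sprintf(
    "<eog_recording> %d channels x %d samples at %g Hz (%.2f s)\n",
    ncol(x$channels), nrow(x$channels), x$sample_rate_hz,
    nrow(x$channels) / x$sample_rate_hz
  ))
  cat("  channels:", paste(colnames(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname eog_recording
#' @param recording an `eog_recording`.
#' @export
channel_labels <- function(recording) colnames(recording$channels)

#' @rdname eog_recording
#' @export
n_samples <- function(recording) nrow(recording$channels)

#' @rdname eog_recording
#' @export
recording_times <- function(recording) {
  recording$start_time_s +
    (seq_len(nrow(recording$channels)) - 1) / recording$sample_rate_hz
}

#' @rdname eog_recording
#' @param label a channel label.
#' @export
get_channel <- function(recording, label) {
  if (!label %in% colnames(recording$channels)) {
    stop("channel not found: ", label)
  }
  recording$channels[, label]
}

# cut a half-open time window [from_s, to_s) out of a recording
window_recording <- function(recording, from_s, to_s) {
  fs <- recording$sample_rate_hz
  i0 <- round((from_s - recording$start_time_s) * fs) + 1
  i1 <- round((to_s - recording$start_time_s) * fs)
  if (i0 < 1 || i1 > nrow(recording$channels)) {
    stop("window outside recording span")
  }
  eog_recording(recording$channels[i0:i1, , drop = FALSE],
                recording$sample_rate_hz, start_time_s = from_s)
}

#' Gaze trace
#'
#' Horizontal and vertical gaze angle series in degrees with a validity mask.
#' Invalid samples (camera dropouts) may be non-finite; they are flagged, not
#' dropped, so resampling stays honest about missing data.
#'
#' @param horizontal_deg,vertical_deg numeric series in degrees
#'   (right/up positive).
#' @param valid logical series; defaults to all finite samples.
#' @param sample_rate_hz sampling rate in Hz (60 for the camera, 125 after
#'   resampling).
#' @param start_time_s time of the first sample in seconds.
#' @return an object of class `gaze_trace`.
#' @export
gaze_trace <- function(horizontal_deg, vertical_deg = NULL, valid = NULL,
                       sample_rate_hz = 125, start_time_s = 0) {
  if (is.null(vertical_deg)) vertical_deg <- numeric(length(horizontal_deg)) * 0
  if (length(horizontal_deg) != length(vertical_deg)) {
    stop("horizontal and vertical series must have equal length")
  }
  if (is.null(valid)) valid <- is.finite(horizontal_deg) & is.finite(vertical_deg)
  if (length(valid) != length(horizontal_deg)) {
    stop("`valid` must match the series length")
  }
  if (!any(valid)) stop("gaze trace has no valid samples")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be positive")
  }
  structure(
    list(horizontal_deg = as.numeric(horizontal_deg),
         vertical_deg = as.numeric(vertical_deg),
         valid = as.logical(valid),
         sample_rate_hz = sample_rate_hz,
         start_time_s = start_time_s),
    class = "gaze_trace"
  )
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf(
    "<gaze_trace> %d samples at %g Hz (%.2f s), %.1f%% valid\n",
    length(x$horizontal_deg), x$sample_rate_hz,
    length(x$horizontal_deg) / x$sample_rate_hz, 100 * mean(x$valid)
  ))
  invisible(x)
}

#' @rdname gaze_trace
#' @param trace a `gaze_trace`.
#' @export
gaze_times <- function(trace) {
  trace$start_time_s + (seq_along(trace$horizontal_deg) - 1) / trace$sample_rate_hz
}

# cut [from_s, to_s) from a gaze trace
window_gaze <- function(trace, from_s, to_s) {
  t <- gaze_times(trace)
  keep <- t >= from_s & t < to_s
  if (!any(keep)) stop("window outside gaze trace span")
  gaze_trace(trace$horizontal_deg[keep], trace$vertical_deg[keep],
             trace$valid[keep], trace$sample_rate_hz, start_time_s = t[keep][1])
}

#' Electrode layout
#'
#' Positions and roles of the electrodes: eight per ear around the ear canal,
#' a reference and a ground, and the periorbital gold-standard electrodes.
#' Coordinates are meters in a head-centered frame (x right, y anterior,
#' z superior).
#'
#' @param layout data frame with columns `label`, `x`, `y`, `z`, `role`
#'   (one of measurement/reference/ground) and `side` (left/right/periorbital).
#' @return a validated `electrode_layout` data frame.
#' @export
electrode_layout <- function(layout) {
  req <- c("label", "x", "y", "z", "role", "side")
  if (!all(req %in% names(layout))) {
    stop("layout needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(layout$label)) stop("electrode labels must be unique")
  if (!all(layout$role %in% c("measurement", "reference", "ground"))) {
    stop("role must be measurement, reference or ground")
  }
  if (!all(layout$side %in% c("left", "right", "periorbital"))) {
    stop("side must be left, right or periorbital")
  }
  aur <- layout[layout$side != "periorbital", ]
  if (sum(aur$role == "reference") != 1 || sum(aur$role == "ground") != 1) {
    stop("layout needs exactly one reference and one ground electrode")
  }
  if (!all(is.finite(as.matrix(layout[, c("x", "y", "z")])))) {
    stop("all electrode positions must be finite")
  }
  class(layout) <- c("electrode_layout", "data.frame")
  layout
}

#' Default periauricular electrode layout
#'
#' Eight electrodes on a ring of radius `ring_radius_m` around each ear canal
#' (in the sagittal plane), numbered so that positions 8 and 1 sit anterior
#' nearest the eyes, plus a reference and ground below each ear, and the four
#' periorbital gold-standard electrodes (outer canthi for horizontal EOG,
#' above/below the left eye for vertical EOG). The published description does
#' not include coordinates, so these are plausible adult head dimensions;
#' every position is overridable by passing a custom layout downstream.
#'
#' @param ring_radius_m ring radius around the ear canal in meters.
#' @param ear_x_m lateral distance of each ear canal from the midline.
#' @param eye_centers 2 x 3 matrix of eye-center positions (left, right).
#' @return an `electrode_layout`.
#' @export
default_electrode_layout <- function(ring_radius_m = 0.05, ear_x_m = 0.0775,
                                     eye_centers = default_eye_centers()) {
  ring_angles <- c(`1` = 30, `2` = 75, `3` = 105, `4` = 150,
                   `5` = -150, `6` = -60, `7` = -105, `8` = 0) * pi / 180
  ring <- function(side, xc) {
    data.frame(
      label = paste0(side, names(ring_angles)),
      x = xc,
      y = ring_radius_m * cos(ring_angles),
      z = ring_radius_m * sin(ring_angles),
      role = "measurement",
      side = if (side == "L") "left" else "right"
    )
  }
  ref_gnd <- data.frame(
    label = c("REF", "GND"),
    x = c(-0.0775, 0.0775),
    y = 0,
    z = -0.07,
    role = c("reference", "ground"),
    side = c("left", "right")
  )
  eye_l <- eye_centers[1, ]
  eye_r <- eye_centers[2, ]
  periorbital <- data.frame(
    label = c("hEOG_left", "hEOG_right", "vEOG_upper", "vEOG_lower"),
    x = c(eye_l[1] - 0.027, eye_r[1] + 0.027, eye_l[1], eye_l[1]),
    y = c(0.085, 0.085, 0.085, 0.085),
    z = c(0, 0, 0.025, -0.025),
    role = "measurement",
    side = "periorbital"
  )
  layout <- rbind(ring("L", -ear_x_m), ring("R", ear_x_m), ref_gnd, periorbital)
  rownames(layout) <- NULL
  electrode_layout(layout)
}

#' @rdname default_electrode_layout
#' @export
default_eye_centers <- function() {
  rbind(left = c(-0.033, 0.08, 0), right = c(0.033, 0.08, 0))
}

# position of one labelled electrode as a length-3 vector
electrode_position <- function(layout, label) {
  i <- match(label, layout$label)
  if (is.na(i)) stop("electrode not in layout: ", label)
  c(layout$x[i], layout$y[i], layout$z[i])
}

#' Read / write a recording as CSV
#'
#' The on-disk format is a plain CSV with a `time_s` column followed by one
#' numeric column per channel (uV). The sample rate is inferred from the
#' median time step.
#'
#' @param path file path.
#' @return for `read_recording_csv`, an [eog_recording()].
#' @export
read_recording_csv <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", header)
  if (header[1] != "time_s") stop("recording CSV must start with a time_s column")
  if (anyDuplicated(header)) stop("duplicated channel header in ", path)
  nf <- count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1) stop("ragged rows in ", path)
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) < 2) stop("recording CSV needs at least 2 samples")
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("non-numeric cells in recording CSV")
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  fs <- 1 / median(dt)
  eog_recording(as.matrix(df[, -1, drop = FALSE]), sample_rate_hz = fs,
                start_time_s = df$time_s[1])
}

#' @rdname read_recording_csv
#' @param recording an `eog_recording`.
#' @export
write_recording_csv <- function(recording, path) {
  df <- data.frame(time_s = recording_times(recording),
                   recording$channels, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a gaze trace as CSV
#'
#' Columns: `time_s`, `h_deg`, `v_deg`, `valid`. Invalid samples keep their
#' (possibly NA) values and `valid = FALSE`.
#'
#' @param path file path.
#' @return for `read_gaze_csv`, a [gaze_trace()].
#' @export
read_gaze_csv <- function(path) {
  df <- read.csv(path)
  req <- c("time_s", "h_deg", "v_deg", "valid")
  if (!all(req %in% names(df))) {
    stop("gaze CSV needs columns: ", paste(req, collapse = ", "))
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  gaze_trace(df$h_deg, df$v_deg, as.logical(df$valid),
             sample_rate_hz = 1 / median(dt), start_time_s = df$time_s[1])
}

#' @rdname read_gaze_csv
#' @param trace a `gaze_trace`.
#' @export
write_gaze_csv <- function(trace, path) {
  df <- data.frame(time_s = gaze_times(trace), h_deg = trace$horizontal_deg,
                   v_deg = trace$vertical_deg, valid = trace$valid)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a homogeneous set of result records to CSV
#'
#' Records must share an identical field set; the column order of the first
#' record is kept, so output bytes are deterministic for fixed input.
#'
#' @param rows a data frame, or a list of identically named lists/records.
#' @param path file path.
#' @export
write_results_table <- function(rows, path) {
  if (is.data.frame(rows)) {
    if (nrow(rows) == 0) stop("no records to write")
    df <- rows
  } else {
    if (length(rows) == 0) stop("no records to write")
    fields <- names(rows[[1]])
    same <- vapply(rows, function(r) identical(names(r), fields), logical(1))
    if (!all(same)) stop("records have mixed field sets")
    df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Statistical test result
#'
#' Lightweight container for a test statistic, its p-value, the test name
#' and the number of observations.
#'
#' @param statistic test statistic (for correlation tests, the coefficient).
#' @param p_value p-value in `[0, 1]`.
#' @param test_name character name of the test.
#' @param n number of observations.
#' @return a `stat_test_result` list.
#' @export
stat_test_result <- function(statistic, p_value, test_name, n) {
  if (!is.finite(p_value) || p_value < 0 || p_value > 1) {
    stop("p_value must be in [0, 1]")
  }
  structure(list(statistic = statistic, p_value = p_value,
                 test_name = test_name, n = as.integer(n)),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g, n = %d\n",
              x$test_name, x$statistic, x$p_value, x$n))
  invisible(x)
}
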