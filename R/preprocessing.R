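# Deterministic signal conditioning. The trial-level EOG chain is
# detrend -> mean filter (50) -> min-max normalization to [-1, 1]; the
# camera chain is interpolate -> resample to 125 Hz -> band-pass
# (0.1-15 Hz, order 5, zero phase) -> mean filter (50) -> normalization.
# All stages preserve length (resampling preserves duration) and are
# deterministic.

#' Remove the least-squares linear trend
#'
#' Subtracts the best-fit line so that the output has zero mean and zero
#' least-squares slope.
#'
#' @param x numeric series of length >= 2.
#' @return detrended series, same length.
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples to detrend")
  t <- seq_len(n)
  fit <- lm.fit(cbind(1, t), x)
  unname(x - fit$fitted.values)
}

#' Centered moving-average (mean) filter
#'
#' Box smoothing with window `length`; edge windows are truncated to the
#' available samples, so the output has the same length as the input.
#'
#' @param x numeric series.
#' @param length window length in samples (default 50).
#' @return smoothed series.
#' @export
mean_filter <- function(x, length = 50) {
  if (length < 1) stop("filter length must be positive")
  n <- base::length(x)
  half_l <- (length - 1) %/% 2
  half_r <- length - 1 - half_l
  cs <- cumsum(c(0, x))
  i0 <- pmax(1, seq_len(n) - half_l)
  i1 <- pmin(n, seq_len(n) + half_r)
  (cs[i1 + 1] - cs[i0]) / (i1 - i0 + 1)
}

#' Min-max normalization to \[-1, 1\]
#'
#' Affine map `x' = 2 (x - min) / (max - min) - 1`, so both interval
#' endpoints are attained. A constant series cannot be scaled; it maps to
#' all zeros and is flagged via the `"degenerate"` attribute, which
#' downstream correlation steps use to exclude the trial.
#'
#' @param x numeric series of length >= 2.
#' @return normalized series with attribute `degenerate` (logical).
#' @export
normalize_unit <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples to normalize")
  r <- range(x)
  # constant up to floating-point residue (e.g. a detrended flat trial)
  if ((r[2] - r[1]) <= 1e-9 * max(1, abs(r[1]), abs(r[2]))) {
    return(structure(numeric(length(x)), degenerate = TRUE))
  }
  structure(2 * (x - r[1]) / (r[2] - r[1]) - 1, degenerate = FALSE)
}

#' @rdname normalize_unit
#' @export
is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))

#' Fill missing gaze samples by linear interpolation
#'
#' Invalid runs are linearly interpolated between the neighbouring valid
#' samples; leading and trailing gaps take the nearest valid value. All
#' samples are valid afterwards.
#'
#' @param trace a [gaze_trace()] with at least 2 valid samples.
#' @return a fully valid [gaze_trace()].
#' @export
interpolate_missing <- function(trace) {
  stopifnot(inherits(trace, "gaze_trace"))
  if (sum(trace$valid) < 2) stop("need at least 2 valid samples to interpolate")
  idx <- seq_along(trace$horizontal_deg)
  fill <- function(x) {
    approx(idx[trace$valid], x[trace$valid], xout = idx, rule = 2)$y
  }
  gaze_trace(fill(trace$horizontal_deg), fill(trace$vertical_deg),
             valid = rep(TRUE, length(idx)),
             sample_rate_hz = trace$sample_rate_hz,
             start_time_s = trace$start_time_s)
}

#' Resample a gaze trace to a target rate
#'
#' Linear interpolation onto a uniform grid spanning the same time range.
#' Run [interpolate_missing()] first: the trace must be fully valid.
#'
#' @param trace a fully valid [gaze_trace()].
#' @param target_hz output rate in Hz (default 125).
#' @return a [gaze_trace()] at `target_hz`.
#' @export
resample_to <- function(trace, target_hz = 125) {
  stopifnot(inherits(trace, "gaze_trace"))
  if (target_hz <= 0) stop("`target_hz` must be positive")
  if (!all(trace$valid)) stop("trace has invalid samples; interpolate first")
  t_in <- gaze_times(trace)
  t_out <- seq(t_in[1], t_in[length(t_in)], by = 1 / target_hz)
  gaze_trace(approx(t_in, trace$horizontal_deg, xout = t_out)$y,
             approx(t_in, trace$vertical_deg, xout = t_out)$y,
             valid = rep(TRUE, length(t_out)),
             sample_rate_hz = target_hz, start_time_s = t_out[1])
}

#' Trial-level EOG conditioning chain
#'
#' `detrend -> mean filter -> normalize to [-1, 1]`, in that order. The
#' band-pass is applied once at ingest on the full recording (see
#' [bandpass_recording()]); the trial chain does not re-filter. A constant
#' trial propagates the degenerate flag.
#'
#' @param x numeric trial series (uV).
#' @param mean_filter_length mean filter window (default 50 samples).
#' @return conditioned series in `[-1, 1]` with attribute `degenerate`.
#' @export
preprocess_eog_trial <- function(x, mean_filter_length = 50) {
  normalize_unit(mean_filter(detrend_linear(x), mean_filter_length))
}

#' Trial-level camera conditioning chain
#'
#' `interpolate missing -> resample to the EOG rate -> band-pass
#' (0.1-15 Hz, order 5, zero phase) -> mean filter -> normalize`. Because a
#' 0.1 Hz high-pass has transients far longer than a 6-s trial, the chain
#' filters the trial together with any surrounding context included in
#' `trace` and trims `trim_s` seconds from each end afterwards; cut trials
#' with context (see [pursuit_trials()]) for best fidelity.
#'
#' @param trace a [gaze_trace()] covering the trial (plus optional context).
#' @param axis `"horizontal"` or `"vertical"`: which angle series to return.
#' @param target_hz EOG rate to resample to (default 125).
#' @param trial_start_s,trial_end_s half-open trial window to keep after
#'   filtering; defaults to the whole trace.
#' @param mean_filter_length mean filter window (default 50 samples).
#' @return conditioned series in `[-1, 1]` with attribute `degenerate`.
#' @export
preprocess_camera_trial <- function(trace, axis = c("horizontal", "vertical"),
                                    target_hz = 125, trial_start_s = NULL,
                                    trial_end_s = NULL,
                                    mean_filter_length = 50) {
  axis <- match.arg(axis)
  res <- resample_to(interpolate_missing(trace), target_hz)
  x <- if (axis == "horizontal") res$horizontal_deg else res$vertical_deg
  x <- bandpass(x, target_hz)
  if (!is.null(trial_start_s)) {
    n_trial <- round((trial_end_s - trial_start_s) * target_hz)
    i0 <- round((trial_start_s - res$start_time_s) * target_hz) + 1
    i0 <- max(1, min(i0, length(x) - n_trial + 1))
    if (n_trial < 2 || i0 + n_trial - 1 > length(x)) {
      stop("trial window exceeds trace length")
    }
    x <- x[i0:(i0 + n_trial - 1)]
  }
  normalize_unit(mean_filter(x, mean_filter_length))
}
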