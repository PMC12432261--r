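# Saccade analysis: epoch extraction around stimulus jumps, automatic
# velocity-threshold labeling of saccade start/end on the gold-standard
# channel, the voltage-deflection statistic, averaged waveforms, and the
# deflection-amplitude correlation.

#' Extract saccade epochs from a recording
#'
#' Cuts one fixed window per `saccade_out` event (and optionally the return
#' saccades), spanning `[onset - pre_onset_s, onset - pre_onset_s +
#' window_s)`; with the defaults (0.75 s pre-onset, 2 s window, ~0.2 s
#' reaction latency) the saccade lands near the window center. Events whose
#' window falls outside the recording are skipped and counted in the
#' `"skipped"` attribute.
#'
#' @param recording an [eog_recording()] (band-passed at ingest).
#' @param schedule the session's `stimulus_schedule`.
#' @param window_s epoch length in seconds (default 2).
#' @param pre_onset_s window start before the stimulus jump (default 0.75).
#' @param include_returns also epoch the center-return saccades
#'   (default `FALSE`; amplitude analyses use outbound saccades only).
#' @param participant_id integer id stored in each epoch.
#' @return list of `saccade_epoch` objects; each has the channels-in-window
#'   matrix `window`, `direction`, `amplitude_deg`, signed
#'   `target_change_deg`, `cycle`, `onset_s` and `fs`.
#' @export
extract_epochs <- function(recording, schedule, window_s = 2,
                           pre_onset_s = 0.75, include_returns = FALSE,
                           participant_id = 1L) {
  kinds <- c("saccade_out", if (include_returns) "saccade_return")
  ev <- schedule$events
  ev <- ev[ev$kind %in% kinds, , drop = FALSE]
  epochs <- list()
  skipped <- 0L
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    from <- e$start_s - pre_onset_s
    win <- tryCatch(window_recording(recording, from, from + window_s),
                    error = function(err) NULL)
    if (is.null(win)) {
      skipped <- skipped + 1L
      next
    }
    change <- signed_amplitude(e$direction, e$amplitude_deg)
    if (e$kind == "saccade_return") change <- -change
    epochs[[length(epochs) + 1]] <- structure(
      list(participant_id = as.integer(participant_id), cycle = e$cycle,
           kind = e$kind, direction = e$direction, axis = e$axis,
           amplitude_deg = e$amplitude_deg, target_change_deg = change,
           onset_s = e$start_s, pre_onset_s = pre_onset_s,
           fs = recording$sample_rate_hz, window = win$channels),
      class = "saccade_epoch")
  }
  structure(epochs, skipped = skipped)
}

# expected deflection sign on the axis-matched gold channel
direction_sign <- function(direction) {
  if (direction %in% c("right", "up")) 1 else -1
}

#' Label saccade start and end in a window
#'
#' Velocity-threshold labeler standing in for manual annotation: the
#' series is box-smoothed, differentiated, and the velocity peak with the
#' sign expected for `direction` is located. Start and end are the nearest
#' samples on either side where the signed velocity falls below
#' `peak_frac` of the peak. The label is invalid when the peak velocity
#' does not exceed `mad_factor` times the MAD of the window velocity --
#' the "no clear start and end" exclusion.
#'
#' @param gold_series the axis-matched gold-standard series in the window
#'   (band-passed).
#' @param direction saccade direction (`left`/`right`/`up`/`down`).
#' @param smooth_len velocity smoothing window in samples (default 11).
#' @param peak_frac velocity threshold as a fraction of the peak
#'   (default 0.15).
#' @param mad_factor validity threshold in MADs of the window velocity
#'   (default 5).
#' @return list with `valid`, `start_idx`, `end_idx` (1-based, inclusive)
#'   and `peak_velocity` (uV/sample, signed).
#' @export
label_saccade <- function(gold_series, direction, smooth_len = 11,
                          peak_frac = 0.15, mad_factor = 5) {
  s <- direction_sign(direction)
  v <- diff(mean_filter(gold_series, smooth_len))
  sv <- s * v
  pk <- which.max(sv)
  vmad <- mad(v)
  if (!is.finite(sv[pk]) || sv[pk] <= max(mad_factor * vmad, 1e-9)) {
    return(list(valid = FALSE, start_idx = NA_integer_, end_idx = NA_integer_,
                peak_velocity = s * sv[pk]))
  }
  thr <- peak_frac * sv[pk]
  below_pre <- which(sv[seq_len(pk)] < thr)
  start_idx <- if (length(below_pre)) max(below_pre) + 1L else 1L
  below_post <- which(sv[pk:length(sv)] < thr)
  end_idx <- if (length(below_post)) pk + min(below_post) - 1L else length(sv)
  # diff index i describes the step between samples i and i+1
  list(valid = TRUE, start_idx = start_idx, end_idx = end_idx + 1L,
       peak_velocity = s * sv[pk])
}

#' Saccade voltage deflection
#'
#' The deflection statistic: the mean of ten samples around the saccade end
#' minus the mean of ten around the start (post-minus-pre, so rightward /
#' upward saccades give positive deflections on channels with positive
#' gain). Three sampling conventions are supported:
#' \describe{
#'   \item{`"flank"`}{(default) the 10 samples immediately before the
#'     labelled start and immediately after the labelled end. Temporally
#'     compact, so the slow tails the 0.1 Hz high-pass leaves from
#'     neighbouring saccades cancel, and the full step height is kept.}
#'   \item{`"span"`}{the first/last 10 samples inside the labelled span;
#'     requires a span of at least 20 samples, otherwise `NA`.}
#'   \item{`"window"`}{the first/last 10 samples of the whole epoch window
#'     (the saccade sitting near its center).}
#' }
#'
#' @param window_series numeric series (one channel of an epoch window).
#' @param start_idx,end_idx labelled saccade span (1-based, inclusive);
#'   ignored for `mode = "window"`.
#' @param mode sampling convention, see above.
#' @param n_avg samples per mean (default 10).
#' @return deflection in uV, or `NA` if the required samples are not
#'   available.
#' @export
deflection <- function(window_series, start_idx, end_idx,
                       mode = c("flank", "span", "window"), n_avg = 10) {
  mode <- match.arg(mode)
  n <- length(window_series)
  if (mode == "window") {
    if (n < 2 * n_avg) return(NA_real_)
    return(mean(window_series[(n - n_avg + 1):n]) -
             mean(window_series[seq_len(n_avg)]))
  }
  if (is.na(start_idx) || is.na(end_idx)) return(NA_real_)
  if (mode == "span") {
    if (end_idx - start_idx + 1 < 2 * n_avg) return(NA_real_)
    return(mean(window_series[(end_idx - n_avg + 1):end_idx]) -
             mean(window_series[start_idx:(start_idx + n_avg - 1)]))
  }
  # flank
  if (start_idx - n_avg < 1 || end_idx + n_avg > n) return(NA_real_)
  mean(window_series[(end_idx + 1):(end_idx + n_avg)]) -
    mean(window_series[(start_idx - n_avg):(start_idx - 1)])
}

# differential series of a montage within an epoch window
epoch_differential <- function(epoch, pair) {
  epoch$window[, pair$channel_a] - epoch$window[, pair$channel_b]
}

#' Deflection records for a set of epochs
#'
#' Labels each epoch on its axis-matched gold-standard channel, computes
#' the voltage deflection of every requested montage (and of the gold
#' channel itself), and attaches the ground-truth angle change: the
#' camera-measured change when a camera trace is supplied, otherwise the
#' stimulus target change. Vertical epochs are processed identically but
#' flagged `reliable = FALSE`, reflecting the weak vertical sensitivity of
#' periauricular montages.
#'
#' @param epochs list of `saccade_epoch`s from [extract_epochs()].
#' @param montages list of [montage_pair()]s to measure.
#' @param gold_channels named character vector mapping axis to gold channel.
#' @param mode deflection sampling convention, see [deflection()].
#' @param camera optional camera [gaze_trace()] for ground-truth changes.
#' @param labeler_args list of arguments passed on to [label_saccade()].
#' @return data frame with one row per epoch: ids, direction, axis,
#'   amplitude, validity, span indices, `angle_change_deg`, `reliable`, and
#'   one deflection column per montage label plus `gold`.
#' @export
saccade_deflections <- function(epochs, montages,
                                gold_channels = c(horizontal = "hEOG",
                                                  vertical = "vEOG"),
                                mode = c("flank", "span", "window"),
                                camera = NULL, labeler_args = list()) {
  mode <- match.arg(mode)
  if (length(epochs) == 0) stop("no epochs")
  labels <- vapply(montages, montage_label, character(1))
  rows <- lapply(epochs, function(ep) {
    gold <- ep$window[, gold_channels[[ep$axis]]]
    lab <- do.call(label_saccade,
                   c(list(gold_series = gold, direction = ep$direction),
                     labeler_args))
    defl <- vapply(montages, function(p) {
      deflection(epoch_differential(ep, p), lab$start_idx, lab$end_idx, mode)
    }, numeric(1))
    names(defl) <- labels
    gold_defl <- deflection(gold, lab$start_idx, lab$end_idx, mode)
    truth <- if (!is.null(camera)) {
      camera_angle_change(camera, ep$onset_s, ep$axis, ep$fs)
    } else {
      ep$target_change_deg
    }
    cbind(
      data.frame(participant = ep$participant_id, cycle = ep$cycle,
                 kind = ep$kind, direction = ep$direction, axis = ep$axis,
                 amplitude_deg = ep$amplitude_deg,
                 target_change_deg = ep$target_change_deg,
                 angle_change_deg = truth,
                 valid = lab$valid && all(is.finite(defl)) &&
                   is.finite(gold_defl),
                 start_idx = lab$start_idx, end_idx = lab$end_idx,
                 reliable = ep$axis == "horizontal",
                 gold = gold_defl),
      as.data.frame(as.list(defl), check.names = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gaze-angle change measured from the camera around a saccade
#'
#' Mean camera angle over `[onset + 0.5 s, onset + 1.2 s]` minus the mean
#' over `[onset - 0.5 s, onset)`, on the saccade's axis; the camera-based
#' ground truth assigned to each deflection record.
#'
#' @param camera a camera [gaze_trace()].
#' @param onset_s stimulus jump time in seconds.
#' @param axis `"horizontal"` or `"vertical"`.
#' @param fs unused; kept for signature stability.
#' @return angle change in degrees.
#' @export
camera_angle_change <- function(camera, onset_s, axis, fs = NULL) {
  t <- gaze_times(camera)
  x <- if (axis == "horizontal") camera$horizontal_deg else camera$vertical_deg
  pre <- camera$valid & t >= onset_s - 0.5 & t < onset_s
  post <- camera$valid & t >= onset_s + 0.5 & t <= onset_s + 1.2
  if (!any(pre) || !any(post)) return(NA_real_)
  mean(x[post]) - mean(x[pre])
}

#' Average saccade waveform
#'
#' Baseline-shifts each epoch's montage signal by its pre-saccade mean (the
#' samples before the labelled start, or the pre-onset portion when no
#' label is available) and returns the pointwise mean and SD across epochs.
#' Constant per-epoch offsets therefore cancel exactly.
#'
#' @param epochs non-empty list of `saccade_epoch`s (one direction-amplitude
#'   group).
#' @param pair a [montage_pair()], or a channel label.
#' @param labeler_args arguments for [label_saccade()].
#' @param gold_channels axis-to-channel map used for labeling.
#' @return list with `mean`, `sd` (series over the window) and `n`.
#' @export
average_waveform <- function(epochs, pair,
                             gold_channels = c(horizontal = "hEOG",
                                               vertical = "vEOG"),
                             labeler_args = list()) {
  if (length(epochs) == 0) stop("empty epoch group")
  series <- vapply(epochs, function(ep) {
    x <- if (inherits(pair, "montage_pair")) {
      epoch_differential(ep, pair)
    } else {
      ep$window[, pair]
    }
    gold <- ep$window[, gold_channels[[ep$axis]]]
    lab <- do.call(label_saccade,
                   c(list(gold_series = gold, direction = ep$direction),
                     labeler_args))
    base_end <- if (lab$valid) lab$start_idx - 1L else round(ep$pre_onset_s * ep$fs)
    base_end <- max(base_end, 1L)
    x - mean(x[seq_len(base_end)])
  }, numeric(nrow(epochs[[1]]$window)))
  series <- matrix(series, ncol = length(epochs))
  list(mean = rowMeans(series),
       sd = apply(series, 1, sd),
       n = length(epochs))
}

#' Resample epochs to a common length
#'
#' Linearly interpolates every channel of every epoch window onto
#' `n_points` samples, preserving relative time.
#'
#' @param epochs list of `saccade_epoch`s.
#' @param n_points target length (>= 20).
#' @return the epochs with resampled windows.
#' @export
interpolate_to_common_length <- function(epochs, n_points) {
  if (n_points < 20) stop("n_points must be at least 20")
  lapply(epochs, function(ep) {
    n <- nrow(ep$window)
    if (n != n_points) {
      s_in <- seq(0, 1, length.out = n)
      s_out <- seq(0, 1, length.out = n_points)
      ep$window <- apply(ep$window, 2, function(x) approx(s_in, x, xout = s_out)$y)
      ep$fs <- ep$fs * (n_points - 1) / (n - 1)
    }
    ep
  })
}

#' Correlation of per-angle ear and gold deflection means
#'
#' Pearson correlation between the per-angle mean deflections of the
#' periauricular montage and the gold standard (default six angles per
#' direction), with the two-sided p-value from the t transform on `n - 2`
#' degrees of freedom.
#'
#' @param ear_means,gold_means equal-length paired mean deflections.
#' @return a [stat_test_result()] with the correlation as `statistic`.
#' @export
deflection_amplitude_correlation <- function(ear_means, gold_means) {
  if (length(ear_means) != length(gold_means)) stop("paired means required")
  if (length(ear_means) < 3) stop("need at least 3 paired means")
  ct <- cor.test(ear_means, gold_means, method = "pearson")
  stat_test_result(unname(ct$estimate), ct$p.value, "pearson",
                   length(ear_means))
}
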