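# Montage selection: lag-constrained correlation of differential electrode
# pairs against gold-standard EOG (max lag 12 samples ~ 100 ms) or
# camera-based gaze (max lag 64 samples ~ 500 ms), aggregated per pair with
# the Fisher z-transformation, then compared across montages with a
# Friedman test and Bonferroni-corrected pairwise Wilcoxon signed-rank
# tests.

#' Differential electrode pair (montage)
#'
#' @param channel_a,channel_b channel labels; the montage signal is
#'   `channel_a - channel_b`.
#' @param orientation `"horizontal"` or `"vertical"` -- the eye-movement
#'   axis the pair is aligned with.
#' @return a `montage_pair` list.
#' @export
montage_pair <- function(channel_a, channel_b,
                         orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  if (identical(channel_a, channel_b)) stop("a montage needs two distinct channels")
  structure(list(channel_a = channel_a, channel_b = channel_b,
                 orientation = orientation),
            class = "montage_pair")
}

#' @rdname montage_pair
#' @param pair a `montage_pair`.
#' @export
montage_label <- function(pair) paste0(pair$channel_a, "-", pair$channel_b)

#' Default candidate montages
#'
#' The horizontally aligned and vertically aligned electrode pairs evaluated
#' by default: horizontal L1-L4, R5-R8, L8-R8, L1-R1, L2-R2, L3-L2, R2-R3;
#' vertical L3-L7, R3-R7, L4-L5, R4-R5. Extensible: any list of
#' [montage_pair()]s can be passed to [rank_montages()].
#'
#' @param orientation `"horizontal"` or `"vertical"`.
#' @return list of `montage_pair`s.
#' @export
default_montages <- function(orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  defs <- if (orientation == "horizontal") {
    list(c("L1", "L4"), c("R5", "R8"), c("L8", "R8"), c("L1", "R1"),
         c("L2", "R2"), c("L3", "L2"), c("R2", "R3"))
  } else {
    list(c("L3", "L7"), c("R3", "R7"), c("L4", "L5"), c("R4", "R5"))
  }
  lapply(defs, function(d) montage_pair(d[1], d[2], orientation))
}

#' Differential (bipolar) signal of a montage
#'
#' @param recording an [eog_recording()].
#' @param pair a [montage_pair()].
#' @return numeric series `channel_a - channel_b` in uV.
#' @export
differential <- function(recording, pair) {
  get_channel(recording, pair$channel_a) - get_channel(recording, pair$channel_b)
}

#' Lag-constrained correlation
#'
#' Pearson correlation of `x` and `y` over every integer lag in
#' `[-max_lag, +max_lag]`, computed on the overlapping segments. Returns
#' the signed correlation at the lag maximizing `|r|`; ties break toward
#' the smaller `|lag|`, then the negative lag. A positive lag means `y`
#' lags `x` by that many samples.
#'
#' @param x,y equal-length numeric series, each longer than `2 * max_lag`.
#' @param max_lag_samples maximum absolute lag in samples.
#' @return list with elements `r`, `lag` and the full `r_by_lag` vector.
#' @export
lagged_correlation <- function(x, y, max_lag_samples) {
  n <- length(x)
  if (length(y) != n) stop("series must have equal length")
  if (n <= 2 * max_lag_samples) stop("series too short for the requested lag range")
  if (is_degenerate(x) || is_degenerate(y) || sd(x) == 0 || sd(y) == 0) {
    stop("degenerate (constant) input; normalization flagged this trial")
  }
  lags <- -max_lag_samples:max_lag_samples
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      cor(x[seq_len(n - l)], y[seq_len(n - l) + l])
    } else {
      cor(x[seq_len(n + l) - l], y[seq_len(n + l)])
    }
  }, numeric(1))
  ok <- is.finite(r)
  ord <- order(-abs(r[ok]), abs(lags[ok]), lags[ok])
  best <- which(ok)[ord[1]]
  list(r = r[best], lag = lags[best],
       r_by_lag = structure(r, names = lags))
}

#' Fisher-z mean of correlation coefficients
#'
#' `tanh(mean(atanh(r)))`. Values at +/-1 are clipped to
#' `+/-(1 - 1e-6)` first so that noiseless (perfect) trials keep a finite
#' Fisher z.
#'
#' @param r_values non-empty numeric vector of correlations.
#' @param clip magnitude at which `|r| = 1` is clipped.
#' @return the Fisher-mean correlation.
#' @export
fisher_mean <- function(r_values, clip = 1 - 1e-6) {
  if (length(r_values) == 0) stop("empty correlation list")
  r <- pmin(pmax(r_values, -clip), clip)
  tanh(mean(atanh(r)))
}

#' Cut pursuit trials out of a session
#'
#' Extracts, for every pursuit event of the requested orientation, the
#' band-passed EOG window, the conditioned gold-standard reference series
#' and the conditioned camera series (camera trials are cut with
#' `camera_context_s` of surrounding recording so the band-pass transient
#' falls outside the trial).
#'
#' @param recording the full [eog_recording()], already band-passed at
#'   ingest (see [bandpass_recording()]).
#' @param camera the session's camera [gaze_trace()] (60 Hz), or `NULL`.
#' @param schedule the session's `stimulus_schedule`.
#' @param orientation `"horizontal"` or `"vertical"`; only pursuit events on
#'   this axis are used.
#' @param gold_channel gold-standard channel label; defaults to `"hEOG"`
#'   for horizontal and `"vEOG"` for vertical.
#' @param camera_context_s context cut around camera trials, seconds.
#' @return list of trials (class `pursuit_trials`), each with elements
#'   `recording` (the trial window), `gold`, `camera` (conditioned series or
#'   `NULL`) and `event`.
#' @export
pursuit_trials <- function(recording, camera, schedule,
                           orientation = c("horizontal", "vertical"),
                           gold_channel = NULL, camera_context_s = 3) {
  orientation <- match.arg(orientation)
  if (is.null(gold_channel)) {
    gold_channel <- if (orientation == "horizontal") "hEOG" else "vEOG"
  }
  ev <- schedule$events
  ev <- ev[ev$kind == "pursuit" & ev$axis == orientation, , drop = FALSE]
  trials <- vector("list", nrow(ev))
  t_max <- max(gaze_times(camera %||% gaze_trace(0, 0, TRUE)))
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    win <- window_recording(recording, e$start_s, e$start_s + e$duration_s)
    gold <- preprocess_eog_trial(get_channel(win, gold_channel))
    cam_series <- NULL
    if (!is.null(camera)) {
      pre <- min(camera_context_s, e$start_s - camera$start_time_s)
      post <- min(camera_context_s, t_max - (e$start_s + e$duration_s))
      pre <- max(pre, 0); post <- max(post, 0)
      cam_win <- window_gaze(camera, e$start_s - pre,
                             e$start_s + e$duration_s + post)
      cam_series <- preprocess_camera_trial(
        cam_win, axis = orientation,
        target_hz = recording$sample_rate_hz,
        trial_start_s = e$start_s, trial_end_s = e$start_s + e$duration_s)
    }
    trials[[i]] <- list(recording = win, gold = gold, camera = cam_series,
                        event = e)
  }
  structure(trials, orientation = orientation, class = "pursuit_trials")
}

#' Rank candidate montages by lag-constrained correlation
#'
#' For every candidate pair and trial, conditions the differential signal
#' with the trial-level EOG chain and correlates it against the reference
#' (gold-standard EOG, max lag 12 samples; or camera gaze, max lag 64
#' samples). Per-trial correlations are aggregated with [fisher_mean()];
#' pairs are ranked by `|mean_r|` descending. Degenerate (flagged) trials
#' are dropped from the affected pair's list.
#'
#' @param trials a [pursuit_trials()] list.
#' @param candidates list of [montage_pair()]s matching the trials'
#'   orientation.
#' @param reference `"gold"` or `"camera"`.
#' @param max_lag_samples maximum lag; defaults to 12 for gold, 64 for
#'   camera.
#' @return data frame with one row per candidate (channel_a, channel_b,
#'   orientation, reference, n_trials, mean_r, median_lag_samples), sorted
#'   by `|mean_r|`; the per-trial correlation and lag matrices are attached
#'   as attributes `r_matrix` and `lag_matrix`.
#' @export
rank_montages <- function(trials, candidates, reference = c("gold", "camera"),
                          max_lag_samples = NULL) {
  reference <- match.arg(reference)
  if (length(trials) < 1) stop("need at least one trial")
  if (length(candidates) == 0) stop("empty candidate list")
  orientation <- attr(trials, "orientation")
  for (p in candidates) {
    if (!identical(p$orientation, orientation)) {
      stop("orientation mismatch: trials are ", orientation,
           " but candidate ", montage_label(p), " is ", p$orientation)
    }
  }
  if (is.null(max_lag_samples)) {
    max_lag_samples <- if (reference == "gold") 12 else 64
  }
  labels <- vapply(candidates, montage_label, character(1))
  r_mat <- matrix(NA_real_, length(trials), length(candidates),
                  dimnames = list(NULL, labels))
  lag_mat <- r_mat
  for (j in seq_along(candidates)) {
    for (i in seq_along(trials)) {
      tr <- trials[[i]]
      ref_series <- if (reference == "gold") tr$gold else tr$camera
      if (is.null(ref_series) || is_degenerate(ref_series)) next
      x <- preprocess_eog_trial(differential(tr$recording, candidates[[j]]))
      if (is_degenerate(x)) next
      lc <- lagged_correlation(x, ref_series, max_lag_samples)
      r_mat[i, j] <- lc$r
      lag_mat[i, j] <- lc$lag
    }
  }
  res <- data.frame(
    montage = labels,
    channel_a = vapply(candidates, function(p) p$channel_a, character(1)),
    channel_b = vapply(candidates, function(p) p$channel_b, character(1)),
    orientation = orientation,
    reference = reference,
    n_trials = colSums(!is.na(r_mat)),
    mean_r = vapply(seq_along(candidates), function(j) {
      r <- r_mat[!is.na(r_mat[, j]), j]
      if (length(r) == 0) NA_real_ else fisher_mean(r)
    }, numeric(1)),
    median_lag_samples = vapply(seq_along(candidates), function(j) {
      l <- lag_mat[!is.na(lag_mat[, j]), j]
      if (length(l) == 0) NA_real_ else median(l)
    }, numeric(1)),
    row.names = make.unique(labels)
  )
  res <- res[order(-abs(res$mean_r)), ]
  attr(res, "r_matrix") <- r_mat
  attr(res, "lag_matrix") <- lag_mat
  res
}

#' Friedman test across montages
#'
#' Tests whether the per-trial correlations differ across montages, using
#' the chi-square approximation with `k - 1` degrees of freedom. Rows with
#' any missing value are removed first (the matrix must stay complete).
#'
#' @param r_matrix trials x montages matrix of correlations.
#' @return a [stat_test_result()].
#' @export
friedman_across_montages <- function(r_matrix) {
  r_matrix <- as.matrix(r_matrix)
  r_matrix <- r_matrix[stats::complete.cases(r_matrix), , drop = FALSE]
  if (ncol(r_matrix) < 2) stop("need at least 2 montages")
  if (nrow(r_matrix) < 2) stop("need at least 2 complete trials")
  ft <- friedman.test(r_matrix)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (!is.finite(stat)) {  # fully tied ranks: no variation to test
    stat <- 0
    p <- 1
  }
  stat_test_result(stat, p, "friedman", nrow(r_matrix))
}

#' Pairwise Wilcoxon signed-rank tests with Bonferroni correction
#'
#' All-pairs two-sided paired signed-rank tests on the columns of
#' `r_matrix`; each p-value is multiplied by the number of comparisons and
#' clipped at 1. Run only after a significant Friedman test (the pipeline
#' gates on p < 0.05). A pair with all-zero differences is undecidable and
#' records p = 1 (flagged in the `"ties"` attribute).
#'
#' @param r_matrix trials x montages matrix of correlations.
#' @return symmetric matrix of corrected p-values (`NA` on the diagonal).
#' @export
pairwise_wilcoxon <- function(r_matrix) {
  r_matrix <- as.matrix(r_matrix)
  r_matrix <- r_matrix[stats::complete.cases(r_matrix), , drop = FALSE]
  k <- ncol(r_matrix)
  if (k < 2) stop("need at least 2 montages")
  m <- k * (k - 1) / 2
  p <- matrix(NA_real_, k, k, dimnames = list(colnames(r_matrix),
                                              colnames(r_matrix)))
  ties <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- r_matrix[, i] - r_matrix[, j]
      if (all(d == 0)) {
        raw <- 1
        ties[i, j] <- ties[j, i] <- TRUE
      } else {
        raw <- suppressWarnings(
          wilcox.test(r_matrix[, i], r_matrix[, j], paired = TRUE)$p.value
        )
      }
      p[i, j] <- p[j, i] <- min(1, raw * m)
    }
  }
  attr(p, "ties") <- ties
  p
}
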