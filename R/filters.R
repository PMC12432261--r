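# Zero-phase Butterworth band-pass filtering via second-order sections.
#
# The transfer-function (b, a) form of a high-order band-pass whose lower edge
# sits at 0.0016 of Nyquist is numerically singular, so the filter is designed
# analytically -- Butterworth low-pass prototype poles, analog band-pass
# transform with prewarped edges, bilinear transform -- and applied as a
# cascade of biquads, each started in its step steady state, on an
# odd-reflection extension of the signal.

#' Design a Butterworth band-pass filter as second-order sections
#'
#' Returns the digital biquad cascade of an order-`order` Butterworth
#' band-pass (total order `2 * order`) with edges `low_hz`/`high_hz` at
#' sampling rate `fs`. Each row of the returned matrix is one section
#' `(b0, b1, b2, 1, a1, a2)`.
#'
#' @param order prototype filter order (the band-pass has twice this order).
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < fs / 2`.
#' @param fs sampling rate in Hz.
#' @return numeric matrix with one second-order section per row.
#' @keywords internal
butter_bandpass_sos <- function(order, low_hz, high_hz, fs) {
  stopifnot(order >= 1, low_hz > 0, high_hz > low_hz, high_hz < fs / 2)
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  sp <- c(vapply(proto, function(p) {
    d <- sqrt((p * bw)^2 - 4 * w0^2 + 0i)
    c((p * bw + d) / 2, (p * bw - d) / 2)
  }, complex(2)))
  zp <- (2 * fs + sp) / (2 * fs - sp)

  tol <- 1e-9
  re <- sort(Re(zp[abs(Im(zp)) < tol]))
  cx <- zp[Im(zp) > tol]
  stopifnot(length(re) %% 2 == 0, length(cx) * 2 + length(re) == 2 * order)
  denoms <- list()
  if (length(re) > 0) {
    for (i in seq(1, length(re), by = 2)) {
      denoms[[length(denoms) + 1]] <- c(1, -(re[i] + re[i + 1]), re[i] * re[i + 1])
    }
  }
  for (p in cx) denoms[[length(denoms) + 1]] <- c(1, -2 * Re(p), Mod(p)^2)

  # each section takes one zero at z = +1 and one at z = -1
  sos <- t(vapply(denoms, function(a) c(1, 0, -1, a), numeric(6)))
  th0 <- 2 * atan(w0 / (2 * fs))  # digital frequency of unit analog response
  g <- Mod(sos_response(sos, exp(1i * th0)))
  sos[1, 1:3] <- sos[1, 1:3] / g
  sos
}

# complex response of a biquad cascade at point(s) z
sos_response <- function(sos, z) {
  h <- rep(1 + 0i, length(z))
  for (i in seq_len(nrow(sos))) {
    s <- sos[i, ]
    h <- h * (s[1] + s[2] / z + s[3] / z^2) / (s[4] + s[5] / z + s[6] / z^2)
  }
  h
}

# steady-state initial filter state for a unit-step input (per section)
biquad_zi <- function(s) {
  b <- s[1:3]; a <- s[4:6]
  zin <- matrix(c(1 + a[2], a[3], -1, 1), 2, 2)
  solve(zin, c(b[2] - a[2] * b[1], b[3] - a[3] * b[1]))
}

# direct-form-II-transposed biquad with initial state
biquad_filter <- function(b, a, x, zi) {
  n <- length(x)
  y <- numeric(n)
  z1 <- zi[1]; z2 <- zi[2]
  for (i in seq_len(n)) {
    yi <- b[1] * x[i] + z1
    z1 <- b[2] * x[i] + z2 - a[2] * yi
    z2 <- b[3] * x[i] - a[3] * yi
    y[i] <- yi
  }
  y
}

# forward-backward filtering of a biquad cascade with odd-reflection padding
sosfiltfilt <- function(sos, x, pad = 300) {
  n <- length(x)
  p <- min(pad, n - 1)
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  for (pass in 1:2) {
    for (i in seq_len(nrow(sos))) {
      zi <- biquad_zi(sos[i, ])
      ext <- biquad_filter(sos[i, 1:3], sos[i, 4:6], ext, zi * ext[1])
    }
    ext <- rev(ext)
  }
  ext[(p + 1):(p + n)]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (zero phase, so downstream lag estimates do not inherit group delay).
#' The effective magnitude response is the squared single-pass response.
#' Output length equals input length.
#'
#' @param x numeric series.
#' @param sample_rate_hz sampling rate in Hz.
#' @param low_hz,high_hz band edges in Hz (defaults 0.1 and 15).
#' @param order filter order (default 5).
#' @return filtered numeric series, same length as `x`.
#' @examples
#' x <- sin(2 * pi * 1 * seq(0, 10, by = 1 / 125))
#' y <- bandpass(x, 125)
#' @export
bandpass <- function(x, sample_rate_hz, low_hz = 0.1, high_hz = 15, order = 5) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (high_hz >= sample_rate_hz / 2) {
    stop("`high_hz` must be below the Nyquist frequency ", sample_rate_hz / 2, " Hz")
  }
  if (low_hz <= 0 || low_hz >= high_hz) stop("band edges out of range: need 0 < low_hz < high_hz")
  if (length(x) <= 3 * order) stop("series too short to filter (need length > ", 3 * order, ")")
  sos <- butter_bandpass_sos(order, low_hz, high_hz, sample_rate_hz)
  sosfiltfilt(sos, x)
}

#' Analytic Butterworth band-pass magnitude response
#'
#' Single-pass magnitude `|H(f)|` of the digital filter that [bandpass()]
#' applies, from the closed-form Butterworth expression with bilinear
#' prewarping (zero-phase application squares this).
#'
#' @inheritParams bandpass
#' @param f_hz frequencies in Hz at which to evaluate.
#' @return numeric vector of magnitudes in `[0, 1]`.
#' @export
butterworth_bandpass_gain <- function(f_hz, sample_rate_hz, low_hz = 0.1,
                                      high_hz = 15, order = 5) {
  w <- 2 * sample_rate_hz * tan(pi * f_hz / sample_rate_hz)
  w1 <- 2 * sample_rate_hz * tan(pi * low_hz / sample_rate_hz)
  w2 <- 2 * sample_rate_hz * tan(pi * high_hz / sample_rate_hz)
  om <- (w^2 - w1 * w2) / (w * (w2 - w1))
  1 / sqrt(1 + om^(2 * order))
}

#' Band-pass filter every channel of a recording
#'
#' Applies [bandpass()] to each channel of a [eog_recording()]; the standard
#' conditioning step at ingest, before trials are cut.
#'
#' @param recording an `eog_recording`.
#' @inheritParams bandpass
#' @return the recording with all channels filtered.
#' @export
bandpass_recording <- function(recording, low_hz = 0.1, high_hz = 15, order = 5) {
  stopifnot(inherits(recording, "eog_recording"))
  sos <- butter_bandpass_sos(order, low_hz, high_hz, recording$sample_rate_hz)
  recording$channels <- apply(recording$channels, 2, function(x) sosfiltfilt(sos, x))
  recording
}
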