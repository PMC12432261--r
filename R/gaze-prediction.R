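# Gaze-angle prediction: ordinary least squares mapping saccade voltage
# deflections (uV) to signed horizontal gaze-angle changes (degrees), with
# leave-one-participant-out evaluation, a per-direction/per-amplitude MAE
# table, and Bland-Altman agreement statistics.

#' Fit a linear gaze-angle model
#'
#' Ordinary least squares of the signed angle change on one or more
#' deflection features. The design matrix must have full rank; collinear
#' features are reported by name.
#'
#' @param records data frame of deflection records (one row per saccade),
#'   e.g. from [saccade_deflections()].
#' @param feature_cols character vector of feature column names.
#' @param target_col name of the signed angle-change column.
#' @return an `angle_model` with `feature_labels`, `coefficients` (per
#'   feature), `intercept` and `training_meta`.
#' @export
fit_angle_model <- function(records, feature_cols,
                            target_col = "angle_change_deg") {
  miss <- setdiff(c(feature_cols, target_col), names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(records[, c(feature_cols, target_col)])
  records <- records[keep, , drop = FALSE]
  y <- records[[target_col]]
  if (length(unique(y)) < 2) stop("need at least 2 distinct target values")
  x <- as.matrix(records[, feature_cols, drop = FALSE])
  design <- cbind(`(Intercept)` = 1, x)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear feature(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm.fit(design, y)
  structure(
    list(feature_labels = feature_cols,
         coefficients = fit$coefficients[feature_cols],
         intercept = unname(fit$coefficients["(Intercept)"]),
         residuals = unname(fit$residuals),
         training_meta = list(n = length(y), target = target_col)),
    class = "angle_model"
  )
}

#' @export
print.angle_model <- function(x, ...) {
  cat(sprintf("<angle_model> %d feature(s), n = %d\n",
              length(x$feature_labels), x$training_meta$n))
  print(c(`(Intercept)` = x$intercept, x$coefficients))
  invisible(x)
}

#' Predict gaze-angle changes from deflection features
#'
#' @param model an `angle_model`.
#' @param features data frame (or named vector) containing every model
#'   feature.
#' @return predicted signed angle change(s) in degrees.
#' @export
predict_angle <- function(model, features) {
  if (!is.data.frame(features)) features <- as.data.frame(as.list(features))
  miss <- setdiff(model$feature_labels, names(features))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(features[, model$feature_labels, drop = FALSE])
  as.numeric(model$intercept + x %*% model$coefficients)
}

#' Cross-validated angle predictions
#'
#' `scheme = "loo"` (default) refits the model leaving one participant out
#' at a time and predicts the held-out participant's saccades -- the
#' one-model-fits-all evaluation. `scheme = "pooled"` fits once on all
#' records and predicts in-sample.
#'
#' @param records deflection records with a `participant` column.
#' @param feature_cols feature column names.
#' @param scheme `"loo"` or `"pooled"`.
#' @param target_col signed angle-change column name.
#' @return numeric vector of predictions aligned with `records` rows (`NA`
#'   where features are missing).
#' @export
cv_predict_angles <- function(records, feature_cols, scheme = c("loo", "pooled"),
                              target_col = "angle_change_deg") {
  scheme <- match.arg(scheme)
  pred <- rep(NA_real_, nrow(records))
  complete <- stats::complete.cases(records[, c(feature_cols, target_col)])
  if (scheme == "pooled") {
    model <- fit_angle_model(records, feature_cols, target_col)
    pred[complete] <- predict_angle(model, records[complete, , drop = FALSE])
    return(pred)
  }
  for (p in unique(records$participant)) {
    test <- records$participant == p & complete
    train <- records$participant != p & complete
    if (!any(test)) next
    if (!any(train)) stop("leave-one-out needs at least 2 participants")
    model <- fit_angle_model(records[train, , drop = FALSE], feature_cols,
                             target_col)
    pred[test] <- predict_angle(model, records[test, , drop = FALSE])
  }
  pred
}

#' Mean-absolute-error table by direction and amplitude
#'
#' Mean and SD of `|predicted - truth|` per direction-amplitude cell, plus
#' per-direction and overall totals. Cells with no observations are simply
#' absent (never reported as zero).
#'
#' @param predicted_deg,truth_deg equal-length numeric vectors (signed
#'   degrees); pairs with a missing value are dropped.
#' @param direction factor/character of saccade directions.
#' @param amplitude_deg unsigned stimulus amplitudes.
#' @return data frame with columns `direction`, `amplitude_deg` (`NA` for
#'   totals), `n`, `mae_deg`, `sd_deg`.
#' @export
evaluate_mae <- function(predicted_deg, truth_deg, direction, amplitude_deg) {
  stopifnot(length(predicted_deg) == length(truth_deg),
            length(direction) == length(predicted_deg),
            length(amplitude_deg) == length(predicted_deg))
  ok <- is.finite(predicted_deg) & is.finite(truth_deg)
  if (!any(ok)) stop("no complete prediction-truth pairs")
  err <- abs(predicted_deg - truth_deg)[ok]
  direction <- direction[ok]
  amplitude_deg <- amplitude_deg[ok]
  rows <- list()
  for (d in unique(direction)) {
    for (a in sort(unique(amplitude_deg[direction == d]))) {
      e <- err[direction == d & amplitude_deg == a]
      rows[[length(rows) + 1]] <- data.frame(
        direction = d, amplitude_deg = a, n = length(e),
        mae_deg = mean(e), sd_deg = if (length(e) > 1) sd(e) else 0)
    }
    e <- err[direction == d]
    rows[[length(rows) + 1]] <- data.frame(
      direction = d, amplitude_deg = NA_real_, n = length(e),
      mae_deg = mean(e), sd_deg = if (length(e) > 1) sd(e) else 0)
  }
  rows[[length(rows) + 1]] <- data.frame(
    direction = "total", amplitude_deg = NA_real_, n = length(err),
    mae_deg = mean(err), sd_deg = if (length(err) > 1) sd(err) else 0)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman agreement statistics
#'
#' Differences are `a - b`; the limits of agreement are
#' `mean +/- 1.96 * SD` with the sample (n-1) standard deviation. The
#' per-point `(mean, diff)` pairs used for plotting are returned alongside.
#'
#' @param a,b equal-length numeric vectors (method A and method B).
#' @return an `agreement_stats` list with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high` and a `points` data frame.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  if (length(a) < 2) stop("need at least 2 paired values")
  d <- a - b
  m <- mean(d)
  s <- sd(d)
  structure(
    list(mean_diff = m, sd_diff = s,
         loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
         points = data.frame(mean = (a + b) / 2, diff = d)),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> mean diff %.3f, LoA [%.3f, %.3f], n = %d\n",
              x$mean_diff, x$loa_low, x$loa_high, nrow(x$points)))
  invisible(x)
}
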