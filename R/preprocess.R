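# Time-series conditioning applied to BOLD channel data and to network
# time courses before Granger analysis. All operations act per channel and
# per subject; the canonical chain is
#   drop -> detrend -> regress confounds -> band-pass -> z-normalize.

#' Drop initial volumes
#'
#' Removes the first `k` time points of every channel (scanner saturation
#' volumes).
#'
#' @param series channels x time matrix.
#' @param k Number of leading time points to drop (default 4).
#' @return Matrix with `ncol(series) - k` columns.
#' @export
drop_initial_volumes <- function(series, k = 4L) {
  stopifnot(is.matrix(series))
  if (!is_count(k, min = 0L)) stopf("k must be a non-negative count")
  if (k >= ncol(series)) {
    stopf("cannot drop %d volumes from a series of length %d", k, ncol(series))
  }
  if (k == 0L) return(series)
  series[, -seq_len(k), drop = FALSE]
}

#' Remove per-channel linear trends
#'
#' Subtracts the ordinary least-squares line (intercept + slope * t) from
#' each channel; output channels have (numerically) zero mean and zero
#' linear trend.
#'
#' @param series channels x time matrix with at least 3 time points.
#' @return Detrended matrix of the same dimensions.
#' @export
detrend_linear <- function(series) {
  stopifnot(is.matrix(series))
  T_ <- ncol(series)
  if (T_ < 3) stopf("detrending needs at least 3 time points")
  X <- cbind(1, seq_len(T_))
  coef <- solve(crossprod(X), crossprod(X, t(series)))
  out <- series - t(X %*% coef)
  dimnames(out) <- dimnames(series)
  out
}

#' Regress confound time series out of every channel
#'
#' Per-channel ordinary least squares on an intercept plus the confound
#' columns; returns the residuals. Collinear confound columns are dropped
#' with a warning.
#'
#' @param series channels x time matrix.
#' @param confounds time x regressors matrix (e.g. 6 motion parameters plus
#'   white-matter and CSF mean signals).
#' @return Residual matrix, same dimensions as `series`.
#' @export
regress_confounds <- function(series, confounds) {
  stopifnot(is.matrix(series))
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != ncol(series)) {
    stopf("confounds have %d rows but the series has %d time points",
          nrow(confounds), ncol(series))
  }
  X <- cbind(`(Intercept)` = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warnf("dropping %d collinear confound column(s)", ncol(X) - qrX$rank)
    X <- X[, sort(keep), drop = FALSE]
    qrX <- qr(X)
  }
  resid <- t(qr.resid(qrX, t(series)))
  dimnames(resid) <- dimnames(series)
  resid
}

#' Zero-phase Butterworth band-pass filter
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift so the lag structure that
#' Granger analysis depends on is preserved.
#'
#' @param series channels x time matrix.
#' @param low_hz,high_hz Passband edges in Hz (defaults 0.008 and 0.15).
#' @param tr_seconds Sampling interval in seconds.
#' @param order Butterworth order per pass (default 2).
#' @return Filtered matrix of the same dimensions.
#' @export
bandpass <- function(series, low_hz = 0.008, high_hz = 0.15, tr_seconds,
                     order = 2L) {
  stopifnot(is.matrix(series))
  if (missing(tr_seconds) || tr_seconds <= 0) {
    stopf("tr_seconds must be supplied and positive")
  }
  nyquist <- 1 / (2 * tr_seconds)
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyquist)) {
    stopf("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
          low_hz, high_hz, nyquist)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  out <- t(apply(series, 1, function(x) signal::filtfilt(bf, x)))
  dimnames(out) <- dimnames(series)
  out
}

#' Normalize each channel to zero mean and unit variance
#'
#' @param series channels x time matrix; every channel must have positive
#'   standard deviation.
#' @return Standardized matrix.
#' @export
znormalize <- function(series) {
  stopifnot(is.matrix(series))
  sds <- apply(series, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(series)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stopf("constant channel(s): %s", paste(bad, collapse = ", "))
  }
  out <- (series - rowMeans(series)) / sds
  dimnames(out) <- dimnames(series)
  out
}

#' Flag motion-censored time points
#'
#' Builds (or validates) a logical censor mask aligned with the series.
#' Censored points are not altered; downstream lagged regressions exclude
#' any regression row whose response or lag window touches a flagged point.
#'
#' @param series channels x time matrix.
#' @param censor Logical vector (length = time points) of flagged points, or
#'   a confound data frame/matrix containing a `censor` column.
#' @return List with `series` (unchanged) and `censor_mask`.
#' @export
censor_motion <- function(series, censor) {
  stopifnot(is.matrix(series))
  if (is.data.frame(censor) || is.matrix(censor)) {
    if (!"censor" %in% colnames(censor)) {
      stopf("confound table has no 'censor' column")
    }
    censor <- as.logical(censor[, "censor"])
  }
  censor <- as.logical(censor)
  if (length(censor) != ncol(series)) {
    stopf("censor mask length %d does not match %d time points",
          length(censor), ncol(series))
  }
  if (all(censor)) stopf("all time points are censored")
  list(series = series, censor_mask = censor)
}

#' Condition every subject of a panel
#'
#' Applies the canonical chain (drop initial volumes, linear detrend,
#' optional confound regression, zero-phase band-pass, z-normalization) to
#' each subject independently, before any temporal concatenation. Filtering
#' precedes concatenation so no filter transient spans two subjects.
#'
#' @param panel A `ts_panel`.
#' @param drop_k Leading volumes to drop (default 4).
#' @param low_hz,high_hz Band-pass edges (defaults 0.008, 0.15 Hz).
#' @param confounds Optional named list: subject id -> time x regressor
#'   matrix (aligned with the series *after* dropping).
#' @param detrend,filter,normalize Toggles for the individual steps.
#' @return The conditioned `ts_panel` with its `log` extended.
#' @export
#' @examples
#' panel <- generate_group_dataset(group_design(n_per_group = 2, seed = 1))
#' conditioned <- preprocess_panel(panel)
#' conditioned$log
preprocess_panel <- function(panel, drop_k = 4L, low_hz = 0.008,
                             high_hz = 0.15, confounds = NULL,
                             detrend = TRUE, filter = TRUE,
                             normalize = TRUE) {
  stopifnot(inherits(panel, "ts_panel"))
  tr <- panel$tr_seconds
  if (filter) {
    nyquist <- 1 / (2 * tr)
    if (!(0 < low_hz && low_hz < high_hz && high_hz < nyquist)) {
      stopf("band [%g, %g] Hz invalid for TR %g s (Nyquist %g Hz)",
            low_hz, high_hz, tr, nyquist)
    }
  }
  steps <- character()
  if (drop_k > 0) {
    panel <- panel_map(panel, function(x, s) drop_initial_volumes(x, drop_k))
    steps <- c(steps, sprintf("drop%d", drop_k))
  }
  if (detrend) {
    panel <- panel_map(panel, function(x, s) detrend_linear(x))
    steps <- c(steps, "detrend")
  }
  if (!is.null(confounds)) {
    panel <- panel_map(panel, function(x, s) {
      cf <- confounds[[s$id]]
      if (is.null(cf)) x else regress_confounds(x, cf)
    })
    steps <- c(steps, "confounds")
  }
  if (filter) {
    panel <- panel_map(panel, function(x, s) {
      bandpass(x, low_hz, high_hz, tr_seconds = tr)
    })
    steps <- c(steps, sprintf("bandpass[%g,%g]", low_hz, high_hz))
  }
  if (normalize) {
    panel <- panel_map(panel, function(x, s) znormalize(x))
    steps <- c(steps, "znormalize")
  }
  panel$log <- c(panel$log, steps)
  panel
}
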