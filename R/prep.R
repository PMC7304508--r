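#' Drop initial volumes from a series
#'
#' Removes the first `k` time points (MRI equilibration volumes) from a 4D
#' array or a voxels x time matrix.
#'
#' @param x 4D array (x, y, z, t) or voxels x time matrix.
#' @param k number of initial volumes to drop.
#' @return same type as `x` with `k` fewer time points.
#' @export
trim_initial_volumes <- function(x, k) {
  k <- as.integer(k)
  nt <- if (is.matrix(x)) ncol(x) else dim(x)[4]
  if (k < 0) stop("k must be nonnegative")
  if (k >= nt) stop("cannot trim ", k, " of ", nt, " volumes")
  if (k == 0) return(x)
  if (is.matrix(x)) x[, -seq_len(k), drop = FALSE]
  else x[, , , -seq_len(k), drop = FALSE]
}

#' Remove a least-squares linear trend from each row
#'
#' @param x voxels x time matrix (or a single series).
#' @return matrix of residuals after projecting out intercept and slope; the
#'   output of every row is orthogonal to `[1, t]`.
#' @export
linear_detrend <- function(x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n < 3) stop("need at least 3 samples to detrend")
  b <- cbind(1, seq_len(n) - (n + 1) / 2)
  b[, 2] <- b[, 2] / sqrt(sum(b[, 2]^2))
  b[, 1] <- b[, 1] / sqrt(n)
  out <- x - (x %*% b) %*% t(b)
  if (vec) out[1, ] else out
}

#' Ideal frequency-domain band-pass filter
#'
#' Zero-phase rectangular mask on the discrete Fourier spectrum: bins with
#' frequency in `[low_hz, high_hz]` are kept, all others (including DC and,
#' when out of band, Nyquist) are zeroed; the mask is applied symmetrically so
#' the output is real.
#'
#' @param x voxels x time matrix (or a single series).
#' @param low_hz,high_hz passband edges in Hz.
#' @param tr_s sampling interval (repetition time) in seconds.
#' @return filtered matrix/series.
#' @export
bandpass <- function(x, low_hz = 0.01, high_hz = 0.1, tr_s = 2) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  nyq <- 1 / (2 * tr_s)
  if (low_hz >= high_hz) stop("low_hz must be below high_hz")
  if (high_hz >= nyq + 1e-12)
    stop("high_hz must be below the Nyquist frequency ", nyq, " Hz")
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * tr_s)
  keep <- f >= low_hz - 1e-12 & f <= high_hz + 1e-12
  xf <- t(stats::mvfft(t(x)))
  xf[, !keep] <- 0
  out <- Re(t(stats::mvfft(t(xf), inverse = TRUE))) / n
  if (vec) out[1, ] else out
}

#' Butterworth band-pass (alternative filter backend)
#'
#' Forward-backward (zero-phase) Butterworth filtering via the signal
#' package; provided as an optional alternative to the ideal filter.
#'
#' @inheritParams bandpass
#' @param order filter order.
#' @export
bandpass_butterworth <- function(x, low_hz = 0.01, high_hz = 0.1, tr_s = 2,
                                 order = 2) {
  if (!requireNamespace("signal", quietly = TRUE))
    stop("the 'signal' package is required for the Butterworth backend")
  nyq <- 1 / (2 * tr_s)
  if (low_hz >= high_hz || high_hz >= nyq)
    stop("invalid passband for Butterworth filter")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  out <- t(apply(x, 1, function(r) signal::filtfilt(bf, r)))
  if (vec) out[1, ] else out
}

#' Z-transform rows to zero mean, unit variance
#'
#' Population (n) denominator so the transform is a fixed linear map of each
#' row. Zero-variance rows are an error here; [prepare_group()] drops them
#' from the common mask instead.
#'
#' @param x voxels x time matrix (or a single series).
#' @return z-scored matrix/series.
#' @export
zscore_rows <- function(x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  m <- rowMeans(x)
  xc <- x - m
  s <- sqrt(rowMeans(xc^2))
  if (any(s == 0)) stop("zero-variance row(s): ",
                        paste(utils::head(which(s == 0)), collapse = ", "))
  out <- xc / s
  if (vec) out[1, ] else out
}

#' Prepare one subject's voxel time series for phase analysis
#'
#' Pipeline: trim initial volumes, per-voxel linear detrend, band-pass
#' (0.01-0.1 Hz by default), z-transform. After band-passing, the in-band
#' component of the trend basis `[1, t]` is also projected out, which makes
#' the detrend + filter stage an exact orthogonal projection (onto the
#' passband intersected with the trend-free subspace): prepared series are
#' both strictly in-band and orthogonal to `[1, t]`, and re-preparing a
#' prepared series is an identity up to floating point. Rows with zero
#' variance after filtering are excluded and reported via the `keep`
#' attribute rather than erroring, so a group-level common mask can be
#' formed.
#'
#' @param x 4D array or voxels x time matrix of raw values.
#' @param tr_s repetition time in seconds.
#' @param n_trim_volumes initial volumes to drop.
#' @param low_hz,high_hz band-pass edges.
#' @param method `"ideal"` (frequency-domain rectangular mask) or
#'   `"butterworth"`.
#' @param mask optional logical volume/vector selecting voxels when `x` is 4D.
#' @return voxels x time matrix of prepared series (zero-variance rows are
#'   zero-filled), with logical attribute `keep` flagging usable rows and
#'   attribute `tr_s`.
#' @export
prepare_series <- function(x, tr_s = 2, n_trim_volumes = 10,
                           low_hz = 0.01, high_hz = 0.1,
                           method = c("ideal", "butterworth"), mask = NULL) {
  method <- match.arg(method)
  m <- as_voxel_matrix(x, mask)
  m <- trim_initial_volumes(m, n_trim_volumes)
  m <- linear_detrend(m)
  bp <- function(z) if (method == "ideal") bandpass(z, low_hz, high_hz, tr_s)
                    else bandpass_butterworth(z, low_hz, high_hz, tr_s)
  m <- bp(m)
  # project out the in-band image of the trend basis so the combined
  # detrend + filter step is idempotent (see Details)
  n <- ncol(m)
  tb <- cbind(rep(1, n), seq_len(n) - (n + 1) / 2)
  tq <- qr.Q(qr(t(bp(t(tb)))))
  m <- m - (m %*% tq) %*% t(tq)
  s <- sqrt(rowMeans((m - rowMeans(m))^2))
  keep <- s > 1e-12
  out <- matrix(0, nrow(m), ncol(m))
  if (any(keep)) out[keep, ] <- zscore_rows(m[keep, , drop = FALSE])
  attr(out, "keep") <- keep
  attr(out, "tr_s") <- tr_s
  out
}

#' Prepare a group of subjects on a common voxel mask
#'
#' Applies [prepare_series()] per subject independently (no cross-subject
#' leakage), then intersects the per-subject usable-voxel flags so every
#' subject contributes every analyzed voxel. If any voxel is dropped a
#' warning reports the count.
#'
#' @param series_list list of 4D arrays or voxels x time matrices.
#' @param ... passed to [prepare_series()].
#' @return list with `data` (list of voxels x time matrices, common rows),
#'   `keep` (logical over input voxel rows) and `tr_s`.
#' @export
prepare_group <- function(series_list, ...) {
  stopifnot(length(series_list) >= 2)
  prepped <- lapply(series_list, prepare_series, ...)
  keeps <- vapply(prepped, attr, logical(nrow(prepped[[1]])), "keep")
  keep <- rowSums(!keeps) == 0
  if (!all(keep))
    warning(sum(!keep), " voxel(s) with zero variance dropped from the ",
            "common mask")
  data <- lapply(prepped, function(p) p[keep, , drop = FALSE])
  list(data = data, keep = keep, tr_s = attr(prepped[[1]], "tr_s"))
}
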