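#' Analytic signal via the Hilbert transform
#'
#' Builds the complex analytic representation `x + i H[x]` of each zero-mean
#' row using the standard FFT construction (positive frequencies doubled,
#' negative frequencies zeroed).
#'
#' @param x zero-mean voxels x time matrix (or a single series).
#' @return complex matrix/series of the same shape.
#' @export
analytic_signal <- function(x) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  mx <- max(abs(x))
  if (mx == 0) stop("phase undefined for an all-zero series")
  if (max(abs(rowMeans(x))) > 1e-6 * max(mx, 1))
    stop("analytic_signal expects zero-mean rows (run prepare_series first)")
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1
    if (n > 2) w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    if (n > 1) w[2:((n + 1) / 2)] <- 2
  }
  xf <- t(stats::mvfft(t(x))) * rep(w, each = nrow(x))
  out <- t(stats::mvfft(t(xf), inverse = TRUE)) / n
  if (vec) out[1, ] else out
}

#' Instantaneous phase of the analytic signal
#'
#' @inheritParams analytic_signal
#' @return matrix/series of phase angles in radians, wrapped to (-pi, pi].
#' @export
analytic_phase <- function(x) {
  a <- analytic_signal(x)
  p <- Arg(a)
  p[p <= -pi] <- pi
  p
}

#' Synchronization of a set of phase angles
#'
#' The mean resultant length `R = |mean(exp(i theta))|` of `N` subject phases,
#' i.e. 1 minus the circular variance: 1 for identical phases, 0 for fully
#' dispersed phases.
#'
#' @param theta numeric vector of `N >= 2` phase angles (radians).
#' @return synchronization value in `[0, 1]`.
#' @export
sync_at_timepoint <- function(theta) {
  if (length(theta) < 2) stop("synchronization needs at least 2 subjects")
  min(Mod(mean(exp(1i * theta))), 1)
}

#' Voxel x time synchronization map across subjects
#'
#' Applies the mean-resultant-length synchronization independently at every
#' (voxel, time point) across the subjects' phase matrices.
#'
#' @param phase_list list (one per subject) of voxels x time phase matrices
#'   of identical shape.
#' @return object of class `sync_map`: voxels x time matrix with values in
#'   `[0, 1]` and attribute `n_subjects`.
#' @export
sync_map <- function(phase_list) {
  n <- length(phase_list)
  if (n < 2) stop("synchronization needs at least 2 subjects")
  d <- dim(phase_list[[1]])
  for (p in phase_list)
    if (!identical(dim(p), d)) stop("phase matrices must share one shape")
  acc <- Reduce(`+`, lapply(phase_list, function(p) exp(1i * p)))
  r <- pmin(Mod(acc) / n, 1)
  structure(r, n_subjects = n, class = c("sync_map", class(r)))
}

#' Pairwise-cosine synchronization (verification oracle)
#'
#' Mean over ordered subject pairs of `cos(theta_s - theta_s')`, computed by
#' direct enumeration. Related to the mean resultant length by
#' `R^2 = 1/N + ((N-1)/N) * pairwise`, and retained purely as an independent
#' cross-check of [sync_at_timepoint()].
#'
#' @param theta numeric vector of `N >= 2` phase angles.
#' @return mean pairwise cosine, in `[-1, 1]`.
#' @export
pairwise_sync_oracle <- function(theta) {
  n <- length(theta)
  if (n < 2) stop("needs at least 2 subjects")
  d <- outer(theta, theta, `-`)
  sum(cos(d[row(d) != col(d)])) / (n * (n - 1))
}

#' Group phase matrices from prepared series
#'
#' Convenience wrapper: [analytic_phase()] for each subject of a prepared
#' group.
#'
#' @param prepared list of prepared voxels x time matrices (zero-mean rows).
#' @return list of phase matrices.
#' @export
group_phases <- function(prepared) {
  lapply(prepared, analytic_phase)
}
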