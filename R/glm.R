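#' Mass-univariate GLM design matrix
#'
#' Condition regressors are boxcars convolved with the canonical double-gamma
#' HRF, sampled on the analyzed (trimmed) volume grid; low-frequency drift is
#' modelled by a discrete cosine basis covering periods longer than
#' `highpass_s`; an intercept is always included and optional nuisance
#' columns (e.g. six motion parameters) are appended.
#'
#' @param design a `block_design`.
#' @param nuisance optional time x k numeric matrix of nuisance regressors.
#' @param highpass_s high-pass cutoff period in seconds.
#' @return matrix with named columns (conditions, `intercept`, `dct1..K`,
#'   nuisance), full column rank.
#' @export
build_design_matrix <- function(design, nuisance = NULL, highpass_s = 128) {
  n <- n_analyzed_volumes(design)
  conds <- design$condition_labels
  xc <- vapply(conds, function(cn) as.numeric(
    convolved_reference(design, cn, hrf_kind = "double_gamma")), numeric(n))
  total_s <- n * design$tr_s
  kmax <- floor(2 * total_s / highpass_s - 1e-9)
  dct <- NULL
  if (kmax >= 1) {
    t0 <- seq_len(n) - 1
    dct <- vapply(seq_len(kmax), function(k)
      cos(pi * k * (2 * t0 + 1) / (2 * n)), numeric(n))
    colnames(dct) <- paste0("dct", seq_len(kmax))
  }
  x <- cbind(xc, intercept = 1, dct)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n) stop("nuisance rows must equal analyzed volumes")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
    x <- cbind(x, nuisance)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  x
}

#' Voxel-wise ordinary least squares
#'
#' @param y time x voxels data matrix (or voxels x time with
#'   `voxels_first = TRUE`).
#' @param x design matrix from [build_design_matrix()].
#' @param voxels_first set when `y` is voxels x time.
#' @return list with `betas` (regressors x voxels, row-named),
#'   `residual_variance` (per voxel) and `df`.
#' @export
fit_voxelwise <- function(y, x, voxels_first = FALSE) {
  if (voxels_first) y <- t(y)
  if (nrow(y) != nrow(x)) stop("data and design matrix lengths differ")
  qx <- qr(x)
  betas <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  df <- nrow(x) - qx$rank
  rownames(betas) <- colnames(x)
  list(betas = betas, residual_variance = colSums(res^2) / df, df = df)
}

#' Group one-sample t-test on contrast maps
#'
#' Computes each subject's contrast value `c' beta` per voxel and a voxel-wise
#' one-sample t statistic across subjects. Voxels with zero between-subject
#' variance yield `NA` and are reported in `flagged`.
#'
#' @param fits list of per-subject [fit_voxelwise()] results (or beta
#'   matrices).
#' @param contrast named numeric vector over design-matrix columns; unnamed
#'   columns get weight 0.
#' @return list with `t` (per-voxel t statistic), `mean_contrast`,
#'   `flagged` (indices of zero-variance voxels) and `df`.
#' @export
contrast_and_group_ttest <- function(fits, contrast) {
  if (length(fits) < 2) stop("group t-test needs at least 2 subjects")
  get_beta <- function(f) if (is.list(f) && !is.null(f$betas)) f$betas else f
  b1 <- get_beta(fits[[1]])
  cw <- numeric(nrow(b1))
  names(cw) <- rownames(b1)
  unknown <- setdiff(names(contrast), rownames(b1))
  if (length(unknown))
    stop("contrast names not in design: ", paste(unknown, collapse = ", "))
  cw[names(contrast)] <- contrast
  con <- t(vapply(fits, function(f) as.numeric(cw %*% get_beta(f)),
                  numeric(ncol(b1))))
  n <- nrow(con)
  m <- colMeans(con)
  s <- apply(con, 2, stats::sd)
  tstat <- ifelse(s == 0, NA_real_, m / (s / sqrt(n)))
  list(t = tstat, mean_contrast = m, flagged = which(s == 0), df = n - 1)
}
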