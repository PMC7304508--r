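#' Spatial ICA of a group synchronization matrix
#'
#' Decomposes the voxels x time synchronization matrix in the spatial-ICA
#' convention: time points are mixture channels, voxels are samples, sources
#' are spatially independent maps and the mixing columns are component
#' synchronization time courses. The estimator is fixed-point negentropy ICA
#' with a tanh contrast and symmetric decorrelation, preceded by PCA
#' whitening to `order` dimensions; results are deterministic given `seed`.
#'
#' Each returned spatial map is z-scored (empirically) and sign-flipped so
#' its skewness is nonnegative, so maps read as clusters of high
#' synchronization; the paired time course is flipped with it.
#'
#' @param sync a `sync_map` or voxels x time matrix (finite values).
#' @param order number of components; if it exceeds the matrix rank it is
#'   reduced to the rank with a warning.
#' @param seed integer seed for the random orthogonal initialisation.
#' @param maxit,tol fixed-point iteration limit and convergence tolerance.
#' @param nonconvergence `"warn"` (default) returns the final iterate with a
#'   warning when the tolerance is not reached — directions spanning a
#'   near-Gaussian subspace have no fixed point, so the rotation there can
#'   wander indefinitely while non-Gaussian sources are stable —
#'   or `"error"` to enforce strict convergence.
#' @return object of class `ica_result`: list with `spatial_maps`
#'   (components x voxels, z-scored), `time_courses` (time x components),
#'   `order`, `seed`, `iterations`, `converged`, `explained_variance`
#'   (fraction of variance retained by the PCA reduction).
#' @export
sync_ica <- function(sync, order = 10, seed = 1, maxit = 200, tol = 1e-4,
                     nonconvergence = c("warn", "error")) {
  nonconvergence <- match.arg(nonconvergence)
  m <- unclass(sync)
  stopifnot(is.matrix(m), all(is.finite(m)))
  v <- nrow(m); nt <- ncol(m)
  if (order >= min(v, nt))
    stop("order must be smaller than min(voxels, time)")
  d <- t(m)                       # time x voxels: channels x samples
  d <- d - rowMeans(d)            # center each channel over voxels
  sv <- svd(d)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (order > rank) {
    warning("requested order ", order, " exceeds matrix rank ", rank,
            "; reduced to rank")
    order <- rank
  }
  u <- sv$u[, seq_len(order), drop = FALSE]
  dd <- sv$d[seq_len(order)]
  explained <- sum(dd^2) / sum(sv$d^2)
  # whitened channels: order x voxels, unit variance, uncorrelated
  z <- t(u) %*% d * sqrt(v) / dd
  w <- with_seed(seed, {
    w0 <- matrix(stats::rnorm(order * order), order, order)
    sw <- svd(w0)
    sw$u %*% t(sw$v)
  })
  it <- 0; converged <- FALSE
  while (it < maxit) {
    it <- it + 1
    wz <- w %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    w1 <- g %*% t(z) / v - diag(gp, order) %*% w
    # symmetric decorrelation
    s <- svd(w1)
    w1 <- s$u %*% t(s$v)
    delta <- max(abs(abs(diag(w1 %*% t(w))) - 1))
    w <- w1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    msg <- paste0("ICA did not converge after ", it, " iterations")
    if (nonconvergence == "error") stop(msg)
    warning(msg, "; returning the final iterate")
  }
  s_maps <- w %*% z                       # order x voxels
  a <- u %*% diag(dd, order) %*% t(w) / sqrt(v)  # time x order
  # empirical z-scoring + nonnegative-skewness sign convention
  for (k in seq_len(order)) {
    sk <- s_maps[k, ]
    sk <- (sk - mean(sk)) / stats::sd(sk)
    if (skewness(sk) < 0) { sk <- -sk; a[, k] <- -a[, k] }
    s_maps[k, ] <- sk
  }
  structure(list(spatial_maps = s_maps, time_courses = a,
                 order = order, seed = seed, iterations = it,
                 converged = converged, explained_variance = explained),
            class = "ica_result")
}

#' @export
print.ica_result <- function(x, ...) {
  cat("Spatial ICA:", x$order, "components,", ncol(x$spatial_maps),
      "voxels,", nrow(x$time_courses), "time points;",
      x$iterations, "iterations,",
      sprintf("%.1f%%", 100 * x$explained_variance),
      "variance retained by PCA\n")
  invisible(x)
}

#' Threshold a z-scored spatial map
#'
#' @param map numeric vector of z values.
#' @param z_threshold voxels with `z > z_threshold` are retained.
#' @return logical voxel mask.
#' @export
threshold_spatial_map <- function(map, z_threshold = 2.3) {
  as.vector(map) > z_threshold
}

#' Match two sets of component maps
#'
#' Maximum-weight one-to-one assignment between the rows of two
#' components x voxels matrices, with weight `|Pearson r|` between maps.
#'
#' @param maps_a,maps_b components x voxels matrices.
#' @return data.frame with columns `a`, `b` (matched indices) and `abs_r`.
#' @export
match_components <- function(maps_a, maps_b) {
  w <- abs(stats::cor(t(maps_a), t(maps_b)))
  b <- hungarian_match(w)
  data.frame(a = seq_len(nrow(maps_a)), b = b,
             abs_r = w[cbind(seq_len(nrow(maps_a)), b)])
}

#' Split-half replicability model-order selection
#'
#' Repeatedly halves the subjects at random, computes each half's
#' synchronization map and spatial ICA at every candidate order, matches the
#' two halves' components one-to-one on absolute spatial correlation
#' (maximum-weight assignment) and scores the order by the mean matched
#' `|r|`. The chosen order maximises the mean score over splits. With an odd
#' subject count the first half receives the extra subject.
#'
#' Both halves of a split use the same ICA initialisation seed, so identical
#' half data yields an identical decomposition and a replicability of 1.
#'
#' @param prepared list of prepared voxels x time matrices (one per subject).
#' @param orders integer vector of candidate model orders.
#' @param n_splits number of random subject splits.
#' @param seed seed controlling the splits and the ICA initialisations.
#' @param ica_args list of extra arguments for [sync_ica()].
#' @param splits optional list of integer vectors, each giving the subjects
#'   of the first half of one split (overrides the random splits).
#' @return list with `chosen_order`, `mean_scores` (named by order) and
#'   `scores` (orders x splits matrix).
#' @export
split_half_replicability <- function(prepared, orders = c(10, 15, 20),
                                     n_splits = 10, seed = 1,
                                     ica_args = list(), splits = NULL) {
  n <- length(prepared)
  if (n < 4) stop("split-half replicability needs at least 4 subjects")
  phases <- group_phases(prepared)
  if (is.null(splits)) {
    perms <- with_seed(seed, replicate(n_splits, sample(n),
                                       simplify = FALSE))
    splits <- lapply(perms, function(idx) idx[seq_len(ceiling(n / 2))])
  } else n_splits <- length(splits)
  scores <- matrix(NA_real_, length(orders), n_splits,
                   dimnames = list(as.character(orders), NULL))
  for (s in seq_len(n_splits)) {
    h1 <- splits[[s]]
    h2 <- setdiff(seq_len(n), h1)
    sm1 <- sync_map(phases[h1])
    sm2 <- sync_map(phases[h2])
    for (k in seq_along(orders)) {
      ic1 <- do.call(sync_ica, c(list(sm1, order = orders[k],
                                      seed = seed + 101 * s), ica_args))
      ic2 <- do.call(sync_ica, c(list(sm2, order = orders[k],
                                      seed = seed + 101 * s), ica_args))
      mm <- match_components(ic1$spatial_maps, ic2$spatial_maps)
      scores[k, s] <- mean(mm$abs_r)
    }
  }
  mean_scores <- rowMeans(scores)
  list(chosen_order = orders[which.max(mean_scores)],
       mean_scores = mean_scores, scores = scores)
}

#' Flag likely artifact components from tissue overlap
#'
#' A component is labelled `unclassified` when more than `artifact_frac` of
#' its suprathreshold voxels fall in white matter, CSF or the brain edge
#' (characteristic artifact territories); components with an empty
#' suprathreshold mask are unclassified with reason "empty". All others are
#' `retained`.
#'
#' @param ica an `ica_result`.
#' @param tissue_masks named list of logical voxel masks; any of `white`,
#'   `csf`, `edge` present are treated as artifact territory.
#' @param z_threshold spatial map threshold.
#' @param artifact_frac artifact-territory fraction above which a component
#'   is unclassified.
#' @return data.frame with columns `component`, `status`, `reason`.
#' @export
flag_artifact_components <- function(ica, tissue_masks,
                                     z_threshold = 2.3,
                                     artifact_frac = 0.5) {
  nv <- ncol(ica$spatial_maps)
  art <- rep(FALSE, nv)
  for (nm in intersect(names(tissue_masks), c("white", "csf", "edge")))
    art <- art | as.logical(tissue_masks[[nm]])
  out <- data.frame(component = seq_len(ica$order),
                    status = "retained", reason = "",
                    stringsAsFactors = FALSE)
  for (k in seq_len(ica$order)) {
    sup <- threshold_spatial_map(ica$spatial_maps[k, ], z_threshold)
    if (!any(sup)) {
      out$status[k] <- "unclassified"; out$reason[k] <- "empty"
    } else {
      frac <- mean(art[sup])
      if (frac > artifact_frac) {
        out$status[k] <- "unclassified"
        out$reason[k] <- sprintf("%.0f%% of suprathreshold voxels in %s",
                                 100 * frac, "white/CSF/edge territory")
      }
    }
  }
  out
}
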