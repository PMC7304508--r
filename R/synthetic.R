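#' Specification of a synthetic multi-subject dataset
#'
#' Describes a group of 4D series with condition-locked network signals
#' shared across subjects, per-subject heterogeneity (response latency shift
#' and amplitude scaling) and AR(1) Gaussian noise. Latency jitter destroys
#' the phase alignment that inter-subject synchronization measures while
#' leaving amplitude (GLM-detectable) structure largely intact, so raising it
#' emulates a condition with high inter-individual response variability.
#'
#' @param grid_dims integer vector of 3 positive voxel-grid dimensions.
#' @param n_subjects number of subjects (>= 2).
#' @param networks list of planted networks, each a list with `mask` (logical
#'   volume of `grid_dims` or linear voxel indices), `conditions` (condition
#'   labels driving the network) and `amplitude` (nonnegative signal scale).
#' @param noise_sd marginal standard deviation of the AR(1) noise.
#' @param ar1_coef AR(1) coefficient in `[0, 1)`.
#' @param latency_jitter_sd_s sd (seconds) of the per-subject response-onset
#'   shift; scalar or one value per network (recycled).
#' @param amplitude_jitter_sd sd of the per-subject multiplicative amplitude
#'   factor `(1 + eta_s)`.
#' @param hrf_kind HRF family used to generate the planted responses.
#' @param seed integer seed; all realisations are deterministic given it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid_dims = c(12, 12, 12), n_subjects = 24,
                           networks = default_networks(grid_dims),
                           noise_sd = 1, ar1_coef = 0.3,
                           latency_jitter_sd_s = 0,
                           amplitude_jitter_sd = 0,
                           hrf_kind = "gamma_no_undershoot",
                           seed = 1) {
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 1),
            noise_sd >= 0, ar1_coef >= 0, ar1_coef < 1,
            all(latency_jitter_sd_s >= 0), amplitude_jitter_sd >= 0)
  nv <- prod(grid_dims)
  networks <- lapply(networks, function(nw) {
    idx <- if (is.logical(nw$mask)) which(nw$mask) else as.integer(nw$mask)
    if (length(idx) == 0 || any(idx < 1) || any(idx > nv))
      stop("network mask does not fit the voxel grid")
    if (nw$amplitude < 0) stop("network amplitude must be nonnegative")
    list(mask = idx, conditions = nw$conditions, amplitude = nw$amplitude)
  })
  lat <- rep_len(latency_jitter_sd_s, length(networks))
  structure(list(grid_dims = as.integer(grid_dims),
                 n_subjects = as.integer(n_subjects),
                 networks = networks, noise_sd = noise_sd,
                 ar1_coef = ar1_coef, latency_jitter_sd_s = lat,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 hrf_kind = hrf_kind, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Three default planted networks
#'
#' Disjoint 3x3x3 cubes in separate octants of the grid, driven by the
#' physical-pain, affective-pain and physical-control conditions with unit
#' amplitude.
#'
#' @param grid_dims voxel grid dimensions (each >= 12 for the default
#'   placements).
#' @return list of network specifications.
#' @export
default_networks <- function(grid_dims = c(12, 12, 12)) {
  stopifnot(all(grid_dims >= 11))
  cube <- function(xr, yr, zr) {
    m <- array(FALSE, grid_dims)
    m[xr, yr, zr] <- TRUE
    m
  }
  hi <- grid_dims - c(3, 3, 3) + 1
  list(
    list(mask = cube(2:4, 2:4, 2:4),
         conditions = "physical_pain", amplitude = 1),
    list(mask = cube(hi[1]:(hi[1] + 2), hi[2]:(hi[2] + 2), 2:4),
         conditions = "affective_pain", amplitude = 1),
    list(mask = cube(hi[1]:(hi[1] + 2), 2:4, hi[3]:(hi[3] + 2)),
         conditions = "physical_control", amplitude = 1))
}

# Per-subject heterogeneity draws, fixed by the spec seed: standard-normal
# latency draws (scaled by the per-network sd) and amplitude factors. Drawing
# standardised values first couples ensembles across jitter levels.
subject_factors <- function(spec) {
  k <- length(spec$networks)
  with_seed(spec$seed, {
    zlat <- matrix(stats::rnorm(spec$n_subjects * k), spec$n_subjects, k)
    zamp <- stats::rnorm(spec$n_subjects)
    list(latency_s = sweep(zlat, 2, spec$latency_jitter_sd_s, `*`),
         amplitude_factor = 1 + spec$amplitude_jitter_sd * zamp)
  })
}

#' Simulate one subject's 4D series
#'
#' Voxel value at (v, t):
#' `sum_k [v in mask_k] * amplitude_k * (1 + eta_s) *
#'  reference_k(onsets shifted by delta_sk)(t) + AR(1) noise`,
#' where `delta_sk ~ N(0, latency_jitter_sd_s_k)` and
#' `eta_s ~ N(0, amplitude_jitter_sd)` are fixed per subject by the spec
#' seed. The series covers all acquired volumes (trimming happens in
#' preparation); the signal sits on an implicit zero baseline and is written
#' unscaled.
#'
#' @param spec a `synthetic_spec`.
#' @param design a `block_design` whose grid the signals are sampled on.
#' @param subject_index subject number in `1..n_subjects`.
#' @return 4D array (x, y, z, t) with `t = n_acquired_volumes`.
#' @export
simulate_subject <- function(spec, design, subject_index) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(design, "block_design"),
            subject_index >= 1, subject_index <= spec$n_subjects)
  fac <- subject_factors(spec)
  nv <- prod(spec$grid_dims)
  nt <- design$n_acquired_volumes
  sig <- matrix(0, nv, nt)
  for (k in seq_along(spec$networks)) {
    nw <- spec$networks[[k]]
    ref <- convolved_reference(
      design, nw$conditions, hrf_kind = spec$hrf_kind,
      onset_shift_s = fac$latency_s[subject_index, k])
    # rebuild on the full (untrimmed) grid so raw series carry every volume
    full <- c(numeric(design$n_trim_volumes), as.numeric(ref))
    amp <- nw$amplitude * fac$amplitude_factor[subject_index]
    sig[nw$mask, ] <- sig[nw$mask, ] +
      matrix(amp * full, length(nw$mask), nt, byrow = TRUE)
  }
  noise <- with_seed(spec$seed * 131L + subject_index, {
    if (spec$noise_sd == 0) matrix(0, nv, nt)
    else {
      innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1_coef^2)
      e <- matrix(stats::rnorm(nv * nt, sd = innov_sd), nt, nv)
      if (spec$ar1_coef > 0) {
        e[1, ] <- stats::rnorm(nv, sd = spec$noise_sd)  # stationary start
        e <- apply(e, 2, function(col)
          stats::filter(col, spec$ar1_coef, method = "recursive",
                        init = col[1] * spec$ar1_coef))
      }
      t(e)
    }
  })
  array(sig + noise, c(spec$grid_dims, nt))
}

#' Simulate a subject group with ground truth
#'
#' @inheritParams simulate_subject
#' @return list with `subjects` (list of 4D arrays) and `truth` (class
#'   `ground_truth`): planted masks (linear indices), conditions, amplitudes,
#'   per-subject realised latency shifts and amplitude factors, and the seed.
#' @export
simulate_group <- function(spec, design) {
  if (spec$n_subjects < 2)
    stop("synchrony is undefined for fewer than 2 subjects")
  fac <- subject_factors(spec)
  subjects <- lapply(seq_len(spec$n_subjects),
                     function(s) simulate_subject(spec, design, s))
  truth <- structure(list(networks = spec$networks,
                          latency_s = fac$latency_s,
                          amplitude_factor = fac$amplitude_factor,
                          grid_dims = spec$grid_dims,
                          seed = spec$seed),
                     class = "ground_truth")
  list(subjects = subjects, truth = truth)
}

#' Logical volume for one planted network
#' @param truth a `ground_truth`.
#' @param k network index.
#' @return logical array of the grid dimensions.
#' @export
network_mask <- function(truth, k) {
  m <- array(FALSE, truth$grid_dims)
  m[truth$networks[[k]]$mask] <- TRUE
  m
}

# run-length encode sorted linear indices as (start, length) pairs
rle_indices <- function(idx) {
  idx <- sort(idx)
  breaks <- c(TRUE, diff(idx) != 1)
  starts <- idx[breaks]
  lengths <- as.integer(tabulate(cumsum(breaks)))
  list(starts = starts, lengths = lengths)
}

#' Write a synthetic dataset to disk
#'
#' One NIfTI-1 4D file per subject, an all-ones brain-mask NIfTI, the events
#' table (TSV) and a ground-truth JSON with masks stored as run-length
#' encoded linear indices.
#'
#' @param group output of [simulate_group()].
#' @param design the `block_design` used for simulation.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_synthetic_dataset <- function(group, design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- design$tr_s
  for (s in seq_along(group$subjects)) {
    img <- RNifti::asNifti(group$subjects[[s]],
                           pixdim = c(1, 1, 1, tr))
    RNifti::writeNifti(img, file.path(dir, sprintf("sub-%02d_bold.nii", s)))
  }
  mask <- array(1L, group$truth$grid_dims)
  RNifti::writeNifti(RNifti::asNifti(mask), file.path(dir, "mask.nii"))
  write_events(design, file.path(dir, "events.tsv"))
  tr_nets <- lapply(group$truth$networks, function(nw) {
    enc <- rle_indices(nw$mask)
    list(conditions = nw$conditions, amplitude = nw$amplitude,
         mask_rle = enc)
  })
  jsonlite::write_json(
    list(grid_dims = group$truth$grid_dims,
         seed = group$truth$seed,
         networks = tr_nets,
         latency_s = group$truth$latency_s,
         amplitude_factor = group$truth$amplitude_factor),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
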