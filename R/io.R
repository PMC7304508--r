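#' Load a group of 4D NIfTI series under a common mask
#'
#' Reads every file, checks that grids and volume counts agree, and extracts
#' voxels x time matrices in a fixed linear voxel order (x fastest, then y,
#' then z — R's native array order), so serialised maps are bit-reproducible.
#'
#' @param files character vector of NIfTI paths (>= 2), or a directory
#'   containing `*_bold.nii[.gz]` files.
#' @param mask_file path to a NIfTI mask (nonzero = in-brain), or `NULL` for
#'   all voxels.
#' @return list with `data` (list of voxels x time matrices), `mask`
#'   (logical vector over the grid), `grid_dims`, `tr_s` (from the first
#'   header, if present) and `files`.
#' @export
load_group <- function(files, mask_file = NULL) {
  if (length(files) == 1 && dir.exists(files))
    files <- sort(list.files(files, "_bold\\.nii(\\.gz)?$",
                             full.names = TRUE))
  if (length(files) < 2) stop("need at least 2 subject files")
  imgs <- lapply(files, RNifti::readNifti)
  dims <- lapply(imgs, dim)
  for (i in seq_along(imgs)) {
    if (length(dims[[i]]) != 4)
      stop("not a 4D series: ", files[i])
    if (!identical(dims[[i]][1:3], dims[[1]][1:3]))
      stop("grid mismatch between ", files[1], " and ", files[i])
    if (dims[[i]][4] != dims[[1]][4])
      stop("volume count mismatch between ", files[1], " and ", files[i])
  }
  grid <- dims[[1]][1:3]
  if (!is.null(mask_file)) {
    mk <- RNifti::readNifti(mask_file)
    if (!identical(dim(mk)[1:3], grid))
      stop("mask grid does not match the series grid")
    mask <- as.vector(mk) != 0
  } else mask <- rep(TRUE, prod(grid))
  pd <- attr(imgs[[1]], "pixdim")
  tr <- if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) pd[4] else NA_real_
  data <- lapply(imgs, function(im)
    matrix(as.vector(im), prod(grid), dims[[1]][4])[mask, , drop = FALSE])
  list(data = data, mask = mask, grid_dims = grid, tr_s = tr, files = files)
}

#' Write a synchronization map as 4D NIfTI plus JSON sidecar
#'
#' @param sync a `sync_map` (voxels x time).
#' @param mask logical vector over the grid selecting the map's rows.
#' @param grid_dims 3-element grid dimensions.
#' @param path output NIfTI path; the sidecar is written as `<path>.json`.
#' @param extra named list merged into the sidecar.
#' @return invisibly, `path`.
#' @export
write_sync_map <- function(sync, mask, grid_dims, path, extra = list()) {
  nt <- ncol(sync)
  vol <- matrix(0, prod(grid_dims), nt)
  vol[as.logical(mask), ] <- unclass(sync)
  RNifti::writeNifti(RNifti::asNifti(array(vol, c(grid_dims, nt))), path)
  side <- c(list(n_subjects = attr(sync, "n_subjects"),
                 n_timepoints = nt,
                 voxel_order = "x-fastest linear index within mask"),
            extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Validates paths and collects the settings of every stage. All referenced
#' paths must exist at validation time.
#'
#' @param subjects_dir directory of subject NIfTI files (`*_bold.nii`).
#' @param events_file BIDS-style events TSV.
#' @param mask_file optional mask NIfTI.
#' @param atlas_file optional integer parcellation NIfTI for overlap reports.
#' @param out_dir output directory.
#' @param tr_s,n_trim_volumes,low_hz,high_hz preparation settings.
#' @param ica_order component count, or vector of candidate orders for
#'   split-half selection.
#' @param n_splits split count when selecting the order.
#' @param z_threshold spatial-map threshold.
#' @param condition_sets named list of reference condition sets.
#' @param m_tests Bonferroni test count (`NULL`: conditions x components).
#' @param seed master seed.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(subjects_dir, events_file, mask_file = NULL,
                            atlas_file = NULL, out_dir = tempfile("isps"),
                            tr_s = 2, n_trim_volumes = 10,
                            low_hz = 0.01, high_hz = 0.1,
                            ica_order = 10, n_splits = 10,
                            z_threshold = 2.3,
                            condition_sets = default_condition_sets(),
                            m_tests = NULL, seed = 1) {
  for (p in c(subjects_dir, events_file, mask_file, atlas_file))
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  structure(list(subjects_dir = subjects_dir, events_file = events_file,
                 mask_file = mask_file, atlas_file = atlas_file,
                 out_dir = out_dir, tr_s = tr_s,
                 n_trim_volumes = n_trim_volumes,
                 low_hz = low_hz, high_hz = high_hz,
                 ica_order = ica_order, n_splits = n_splits,
                 z_threshold = z_threshold,
                 condition_sets = condition_sets, m_tests = m_tests,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full ISPS pipeline
#'
#' Stages: load subjects -> per-subject preparation (trim, detrend,
#' band-pass, z-transform) -> analytic phases -> group synchronization map ->
#' spatial ICA (with optional split-half order selection) -> artifact
#' flagging -> component-reference association (Pearson, Bonferroni) plus
#' pain-vs-control Fisher z contrasts -> optional atlas overlap. Writes the
#' synchronization map, component maps and time courses, association tables
#' and a machine-readable summary; every output embeds the seed and a config
#' hash. Deterministic given the config.
#'
#' @param config a `pipeline_config`.
#' @return invisible list bundle with elements `design`, `prepared`, `sync`,
#'   `ica`, `labels`, `association`, `contrasts`, `replicability` (when order
#'   selection ran), `overlap` (when an atlas was given) and `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  grp <- stage("load", load_group(config$subjects_dir, config$mask_file))
  nt <- ncol(grp$data[[1]])
  design <- stage("design", read_events(
    config$events_file, tr_s = config$tr_s, n_acquired_volumes = nt,
    n_trim_volumes = config$n_trim_volumes))
  prep <- stage("prepare", prepare_group(
    grp$data, tr_s = config$tr_s, n_trim_volumes = config$n_trim_volumes,
    low_hz = config$low_hz, high_hz = config$high_hz))
  phases <- stage("phase", group_phases(prep$data))
  sm <- stage("sync", sync_map(phases))

  repl <- NULL
  order <- config$ica_order
  if (length(order) > 1) {
    repl <- stage("order-selection", split_half_replicability(
      prep$data, orders = order, n_splits = config$n_splits,
      seed = config$seed))
    order <- repl$chosen_order
  }
  ica <- stage("ica", sync_ica(sm, order = order, seed = config$seed))
  labels <- stage("artifact-flagging",
                  flag_artifact_components(ica, list(),
                                           z_threshold = config$z_threshold))
  retained <- labels$component[labels$status == "retained"]
  refs <- stage("references", reference_set(design, config$condition_sets))
  assoc <- stage("association", component_condition_correlations(
    ica, refs, m_tests = config$m_tests, components = retained))
  contrasts <- stage("contrasts", do.call(rbind, lapply(retained, function(k) {
    rbind(condition_contrast(assoc, k, "physical_pain", "physical_control"),
          condition_contrast(assoc, k, "affective_pain", "affective_control"))
  })))
  ov <- NULL
  if (!is.null(config$atlas_file)) {
    atlas <- RNifti::readNifti(config$atlas_file)
    ov <- stage("overlap", overlap_report(
      ica, as.integer(atlas)[grp$mask][prep$keep], config$z_threshold))
  }

  # artifacts
  mask_kept <- grp$mask
  mask_kept[grp$mask] <- prep$keep
  cfg_hash <- object_hash(unclass(config))
  write_sync_map(sm, mask_kept, grp$grid_dims,
                 file.path(config$out_dir, "sync_map.nii"),
                 extra = list(seed = config$seed, config_hash = cfg_hash))
  utils::write.table(
    data.frame(time = seq_len(nrow(ica$time_courses)), ica$time_courses),
    file.path(config$out_dir, "time_courses.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(assoc, file.path(config$out_dir, "association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(contrasts, file.path(config$out_dir, "contrasts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(seed = config$seed, config_hash = cfg_hash,
                  n_subjects = length(grp$data),
                  n_voxels = sum(mask_kept), n_timepoints = ncol(sm),
                  ica_order = ica$order,
                  retained_components = retained,
                  replicability = if (!is.null(repl)) repl$mean_scores,
                  mean_sync = mean(sm))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(design = design, prepared = prep, sync = sm, ica = ica,
                 labels = labels, association = assoc,
                 contrasts = contrasts, replicability = repl, overlap = ov,
                 summary = summary))
}
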