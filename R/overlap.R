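#' Percentage overlap of a voxel mask with parcellation labels
#'
#' For each integer label, the percentage of the mask's voxels carrying that
#' label; voxels with label 0 (or outside all labels) are reported as
#' `unassigned`. Percentages sum to 100.
#'
#' @param mask logical vector/array of suprathreshold voxels.
#' @param labels integer vector/array of parcellation labels on the same
#'   grid (0 = unassigned).
#' @param label_names optional named character vector mapping label ids to
#'   names.
#' @return data.frame with columns `label`, `name`, `percent`.
#' @export
percent_overlap <- function(mask, labels, label_names = NULL) {
  mask <- as.logical(mask)
  labels <- as.integer(labels)
  if (length(mask) != length(labels))
    stop("mask and label volume must share one grid")
  if (!any(mask)) stop("empty mask has no defined overlap")
  lab <- labels[mask]
  ids <- sort(unique(labels[labels > 0]))
  pct <- vapply(ids, function(l) 100 * mean(lab == l), numeric(1))
  unassigned <- 100 * mean(lab <= 0)
  nm <- if (is.null(label_names)) as.character(ids)
        else unname(label_names[as.character(ids)])
  out <- data.frame(label = c(ids, 0L),
                    name = c(nm, "unassigned"),
                    percent = c(pct, unassigned),
                    stringsAsFactors = FALSE)
  out
}

#' Atlas overlap report for thresholded ICA components
#'
#' @param ica an `ica_result`.
#' @param labels integer parcellation over the analysis voxels (same order
#'   as the ICA spatial maps).
#' @param z_threshold spatial map threshold.
#' @param label_names optional label-id to name mapping.
#' @return data.frame of per-component overlap rows (components with an
#'   empty suprathreshold mask are skipped with a warning).
#' @export
overlap_report <- function(ica, labels, z_threshold = 2.3,
                           label_names = NULL) {
  out <- list()
  for (k in seq_len(ica$order)) {
    sup <- threshold_spatial_map(ica$spatial_maps[k, ], z_threshold)
    if (!any(sup)) {
      warning("component ", k, " has no suprathreshold voxels; skipped")
      next
    }
    row <- percent_overlap(sup, labels, label_names)
    row$component <- k
    out[[length(out) + 1]] <- row
  }
  do.call(rbind, out)
}
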