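#' Blocked task design
#'
#' Container for the temporal skeleton of a blocked fMRI paradigm: labelled
#' condition blocks with onsets and durations (seconds), the repetition time,
#' and the acquired/trimmed volume counts. All downstream reference functions
#' are built from this object, so any block order read from an events table is
#' analysed identically to the shipped default order.
#'
#' @param blocks data.frame with columns `onset`, `duration` (seconds) and
#'   `condition` (character), one row per block, time-ordered.
#' @param condition_labels character vector of valid condition labels.
#' @param tr_s repetition time in seconds.
#' @param n_acquired_volumes number of volumes acquired in the run.
#' @param n_trim_volumes number of initial volumes discarded before analysis.
#' @return An object of class `block_design`.
#' @export
block_design <- function(blocks,
                         condition_labels = unique(blocks$condition),
                         tr_s = 2,
                         n_acquired_volumes = 218,
                         n_trim_volumes = 10) {
  stopifnot(is.data.frame(blocks),
            all(c("onset", "duration", "condition") %in% names(blocks)))
  blocks <- blocks[, c("onset", "duration", "condition")]
  blocks$condition <- as.character(blocks$condition)
  if (!all(blocks$condition %in% condition_labels)) {
    bad <- setdiff(blocks$condition, condition_labels)
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  }
  if (is.unsorted(blocks$onset, strictly = TRUE))
    stop("blocks must be strictly time-ordered by onset")
  ends <- blocks$onset + blocks$duration
  if (any(blocks$onset[-1] < ends[-nrow(blocks)]))
    stop("blocks must not overlap")
  total_s <- n_acquired_volumes * tr_s
  if (ends[nrow(blocks)] > total_s + 1e-9)
    stop("last block ends after the acquired run (", ends[nrow(blocks)],
         " s > ", total_s, " s)")
  if (n_trim_volumes >= n_acquired_volumes)
    stop("n_trim_volumes must be smaller than n_acquired_volumes")
  structure(list(blocks = blocks,
                 condition_labels = condition_labels,
                 tr_s = tr_s,
                 n_acquired_volumes = as.integer(n_acquired_volumes),
                 n_trim_volumes = as.integer(n_trim_volumes)),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat("Blocked design:", nrow(x$blocks), "blocks,",
      length(x$condition_labels), "conditions, TR", x$tr_s, "s,",
      x$n_acquired_volumes, "acquired volumes (", x$n_trim_volumes,
      "trimmed )\n")
  invisible(x)
}

#' Number of analyzed volumes of a design
#' @param design a `block_design`.
#' @return integer count of volumes after trimming.
#' @export
n_analyzed_volumes <- function(design) {
  design$n_acquired_volumes - design$n_trim_volumes
}

# Fixed pseudorandom default order (4 blocks per condition) and gap sequence
# (five each of 8/10/12 s). 20 s lead-in + 16x16 s blocks + 150 s of gaps +
# 10 s tail = 436 s at TR 2 s = 218 volumes.
.default_condition_order <- c(
  "physical_pain", "affective_control", "physical_control", "affective_pain",
  "physical_control", "affective_pain", "physical_pain", "affective_control",
  "affective_pain", "physical_pain", "affective_control", "physical_control",
  "affective_pain", "physical_control", "physical_pain", "affective_control")

.default_gaps <- c(10, 8, 12, 10, 12, 8, 10, 12, 8, 10, 8, 12, 10, 8, 12)

#' Default 4-condition blocked pain-empathy paradigm
#'
#' Sixteen 16 s picture blocks (4 per condition: physical/affective pain and
#' their matched control conditions) separated by jittered 8/10/12 s rest
#' gaps, with a 20 s lead-in; 436 s total acquired in 218 volumes at TR 2 s,
#' of which the first 10 are discarded. The shipped block order is one fixed
#' pseudorandom sequence; pass `seed` to draw a different order with the same
#' condition and gap counts.
#'
#' @param seed optional integer; when supplied, condition order and gap order
#'   are reshuffled reproducibly (counts preserved).
#' @return A `block_design`.
#' @examples
#' d <- default_block_design()
#' table(d$blocks$condition)
#' @export
default_block_design <- function(seed = NULL) {
  conds <- .default_condition_order
  gaps <- .default_gaps
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    conds <- sample(conds)
    gaps <- sample(gaps)
  }
  onsets <- 20 + c(0, cumsum(16 + gaps))
  blocks <- data.frame(onset = onsets, duration = 16, condition = conds,
                       stringsAsFactors = FALSE)
  block_design(blocks,
               condition_labels = c("physical_pain", "affective_pain",
                                    "physical_control", "affective_control"),
               tr_s = 2, n_acquired_volumes = 218, n_trim_volumes = 10)
}

#' Boxcar regressor on an upsampled grid
#'
#' Value 1 inside blocks belonging to `conditions`, 0 elsewhere, sampled on a
#' fine grid of `upsample_per_tr` samples per TR starting at time 0 of the
#' acquired run (before trimming).
#'
#' @param design a `block_design`.
#' @param conditions character vector of condition labels (may be empty).
#' @param upsample_per_tr samples per TR of the fine grid.
#' @param onset_shift_s shift (seconds) applied to every selected block onset,
#'   used to model subject-level response latency.
#' @return numeric vector of 0/1 values, length
#'   `n_acquired_volumes * upsample_per_tr`.
#' @export
boxcar_regressor <- function(design, conditions, upsample_per_tr = 10,
                             onset_shift_s = 0) {
  stopifnot(inherits(design, "block_design"))
  unknown <- setdiff(conditions, design$condition_labels)
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
  dt <- design$tr_s / upsample_per_tr
  n <- design$n_acquired_volumes * upsample_per_tr
  times <- (seq_len(n) - 1) * dt
  box <- numeric(n)
  sel <- design$blocks$condition %in% conditions
  for (i in which(sel)) {
    on <- design$blocks$onset[i] + onset_shift_s
    off <- on + design$blocks$duration[i]
    box[times >= on - 1e-9 & times < off - 1e-9] <- 1
  }
  box
}

#' Hemodynamic response kernel
#'
#' Unit-sum HRF kernel sampled at interval `dt_s`. `gamma_no_undershoot` is a
#' single gamma density parameterised by its mean lag and standard deviation
#' (width); `double_gamma` is the canonical difference of two gamma densities
#' with a late negative undershoot lobe.
#'
#' @param kind `"gamma_no_undershoot"` or `"double_gamma"`.
#' @param dt_s sampling interval in seconds.
#' @param lag_s,width_s mean lag and width (sd) of the single-gamma kernel.
#' @param peak_s,undershoot_s,ratio canonical double-gamma parameters: time to
#'   peak, time to undershoot peak, positive-to-negative lobe ratio.
#' @param duration_s kernel support in seconds.
#' @return numeric kernel summing to 1.
#' @export
hrf_kernel <- function(kind = c("gamma_no_undershoot", "double_gamma"),
                       dt_s = 0.2, lag_s = 6, width_s = 3,
                       peak_s = 6, undershoot_s = 16, ratio = 6,
                       duration_s = 32) {
  kind <- match.arg(kind)
  t <- seq(0, duration_s, by = dt_s)
  if (kind == "gamma_no_undershoot") {
    if (lag_s <= 0 || width_s <= 0)
      stop("lag_s and width_s must be positive")
    shape <- (lag_s / width_s)^2
    scale <- width_s^2 / lag_s
    k <- stats::dgamma(t, shape = shape, scale = scale)
  } else {
    if (peak_s <= 0 || undershoot_s <= 0 || ratio <= 0)
      stop("double-gamma parameters must be positive")
    k <- stats::dgamma(t, shape = peak_s, scale = 1) -
      stats::dgamma(t, shape = undershoot_s, scale = 1) / ratio
  }
  k / sum(k)
}

#' HRF-convolved reference function on the analyzed volume grid
#'
#' Builds the condition boxcar on an upsampled grid, convolves it with the
#' requested HRF kernel, samples the result at each acquired volume time and
#' drops the first `n_trim_volumes` samples, so the reference aligns with
#' trimmed, analyzed data.
#'
#' @inheritParams boxcar_regressor
#' @param hrf_kind HRF kernel type, see [hrf_kernel()].
#' @param hrf_args list of extra arguments forwarded to [hrf_kernel()].
#' @return numeric vector of length `n_analyzed_volumes(design)` with
#'   attribute `conditions`.
#' @export
convolved_reference <- function(design, conditions,
                                hrf_kind = "gamma_no_undershoot",
                                upsample_per_tr = 10, onset_shift_s = 0,
                                hrf_args = list()) {
  box <- boxcar_regressor(design, conditions, upsample_per_tr, onset_shift_s)
  dt <- design$tr_s / upsample_per_tr
  k <- do.call(hrf_kernel, c(list(kind = hrf_kind, dt_s = dt), hrf_args))
  y <- stats::convolve(box, rev(k), type = "open")[seq_along(box)]
  vol_idx <- 1 + (seq_len(design$n_acquired_volumes) - 1) * upsample_per_tr
  ref <- y[vol_idx]
  if (design$n_trim_volumes > 0)
    ref <- ref[-seq_len(design$n_trim_volumes)]
  attr(ref, "conditions") <- conditions
  ref
}

#' Default reference condition sets
#'
#' The eight condition sets used for component association in the default
#' paradigm: the four single conditions plus the physical, affective, pain and
#' control unions.
#'
#' @return named list of character vectors of condition labels.
#' @export
default_condition_sets <- function() {
  list(physical_pain    = "physical_pain",
       affective_pain   = "affective_pain",
       physical_control = "physical_control",
       affective_control = "affective_control",
       physical_all = c("physical_pain", "physical_control"),
       affective_all = c("affective_pain", "affective_control"),
       pain_all = c("physical_pain", "affective_pain"),
       control_all = c("physical_control", "affective_control"))
}

#' Matrix of reference functions
#'
#' One column per condition set, sampled on the analyzed volume grid.
#'
#' @inheritParams convolved_reference
#' @param condition_sets named list of condition-label vectors.
#' @return numeric matrix, `n_analyzed_volumes(design)` rows.
#' @export
reference_set <- function(design, condition_sets = default_condition_sets(),
                          hrf_kind = "gamma_no_undershoot", ...) {
  refs <- vapply(condition_sets,
                 function(cs) as.numeric(
                   convolved_reference(design, cs, hrf_kind = hrf_kind, ...)),
                 numeric(n_analyzed_volumes(design)))
  colnames(refs) <- names(condition_sets)
  refs
}

#' Read a block design from a BIDS-style events table
#'
#' Tab-separated file with header columns `onset`, `duration`, `trial_type`
#' (seconds, period decimal separator).
#'
#' @param path file path.
#' @inheritParams block_design
#' @return A `block_design`.
#' @export
read_events <- function(path, tr_s = 2, n_acquired_volumes = 218,
                        n_trim_volumes = 10, condition_labels = NULL) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop("events file must have columns: ", paste(need, collapse = ", "))
  blocks <- data.frame(onset = as.numeric(ev$onset),
                       duration = as.numeric(ev$duration),
                       condition = as.character(ev$trial_type),
                       stringsAsFactors = FALSE)
  if (is.null(condition_labels)) condition_labels <- unique(blocks$condition)
  block_design(blocks, condition_labels, tr_s, n_acquired_volumes,
               n_trim_volumes)
}

#' Write a block design as a BIDS-style events table
#' @param design a `block_design`.
#' @param path output file path.
#' @export
write_events <- function(design, path) {
  ev <- data.frame(onset = design$blocks$onset,
                   duration = design$blocks$duration,
                   trial_type = design$blocks$condition)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
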