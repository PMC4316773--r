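# Reduction of trial-level voxel data to one response pattern per scene.

#' Construct a trial-pattern array
#'
#' Container for trial-level voxel responses within one region of interest:
#' a 4-D array indexed (scene, repetition, timepoint, voxel) with uniformly
#' spaced timepoints starting at 0 s after stimulus onset.
#'
#' @param responses numeric 4-D array `[scene, repetition, timepoint, voxel]`.
#' @param spacing timepoint spacing in seconds.
#' @param roi label of the region of interest.
#' @param voxel_order character note recording how voxels were linearized
#'   from the acquisition grid.
#' @return a `trial_pattern_array` object (list with `responses`, `onsets`,
#'   `spacing`, `roi`, `voxel_order`).
#' @export
trial_pattern_array <- function(responses, spacing = 2, roi = "ROI",
                                voxel_order = "as supplied") {
  d <- dim(responses)
  if (length(d) != 4L) {
    stop("`responses` must be a 4-D array (scene, repetition, timepoint, voxel)",
         call. = FALSE)
  }
  structure(list(responses = responses,
                 onsets = (seq_len(d[3]) - 1) * spacing,
                 spacing = spacing, roi = roi, voxel_order = voxel_order),
            class = "trial_pattern_array")
}

#' @export
print.trial_pattern_array <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf(
    "trial_pattern_array [%s]: %d scenes x %d repetitions x %d timepoints (%g s spacing) x %d voxels\n",
    x$roi, d[1], d[2], d[3], x$spacing, d[4]))
  invisible(x)
}

#' Extract masked voxels from acquisition volumes
#'
#' Subsets a stack of 3-D acquisition volumes to the voxels inside a binary
#' region-of-interest mask and reshapes the result into a
#' [trial_pattern_array()].  Voxels are linearized in a fixed row-major
#' order over the grid (x slowest, z fastest), recorded in the output so
#' patterns are reproducible across runs.
#'
#' @param volumes 4-D numeric array `[x, y, z, volume]`, one 3-D volume per
#'   acquired trial-timepoint (e.g. as read from NIfTI with
#'   [read_nifti_volumes()]).
#' @param mask logical (or 0/1) 3-D array matching the volume grid.
#' @param index data frame with one row per volume and columns `scene`,
#'   `repetition`, `timepoint` (all 1-based), mapping each volume to its
#'   place in the design.
#' @param spacing timepoint spacing in seconds.
#' @param roi label for the output.
#' @return a [trial_pattern_array()] whose voxel axis holds the mask-true
#'   positions.
#' @export
apply_roi_mask <- function(volumes, mask, index, spacing = 2, roi = "ROI") {
  dv <- dim(volumes)
  if (length(dv) != 4L) stop("`volumes` must be 4-D", call. = FALSE)
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), dv[1:3])) {
    stop("mask grid does not match volume grid", call. = FALSE)
  }
  if (!any(mask)) stop("empty mask", call. = FALSE)
  need <- c("scene", "repetition", "timepoint")
  if (!all(need %in% names(index)) || nrow(index) != dv[4]) {
    stop("`index` needs columns scene/repetition/timepoint, one row per volume",
         call. = FALSE)
  }
  # row-major linearization: x slowest, z fastest
  pos <- which(mask)                        # column-major linear positions
  arr <- which(mask, arr.ind = TRUE)
  ord <- order(arr[, 1], arr[, 2], arr[, 3])
  pos <- pos[ord]

  n_scene <- max(index$scene)
  n_rep <- max(index$repetition)
  n_time <- max(index$timepoint)
  out <- array(NA_real_, c(n_scene, n_rep, n_time, length(pos)))
  flat <- matrix(volumes, prod(dv[1:3]), dv[4])
  for (vi in seq_len(dv[4])) {
    out[index$scene[vi], index$repetition[vi], index$timepoint[vi], ] <-
      flat[pos, vi]
  }
  if (anyNA(out)) {
    warning("design cells without a matching volume remain NA", call. = FALSE)
  }
  trial_pattern_array(out, spacing = spacing, roi = roi,
                      voxel_order = "row-major over grid (x slowest, z fastest)")
}

#' Reduce trials to one pattern per scene
#'
#' Averages trial-level responses over repetitions, then over the
#' timepoints whose onset lies inside the closed `window` (default 6-8 s,
#' the peak of a slow event-related response sampled every 2 s), producing
#' one voxel pattern per scene.  Repetitions with missing data are averaged
#' over the available repetitions and the per-scene counts are reported.
#'
#' @param trials a [trial_pattern_array()].
#' @param window closed time window in seconds.
#' @return a `pattern_matrix`: list with `patterns` (scenes x voxels
#'   matrix), `roi`, `window`, `timepoints_used` (onsets averaged).
#' @export
build_scene_patterns <- function(trials, window = c(6, 8)) {
  stopifnot(inherits(trials, "trial_pattern_array"))
  stopifnot(length(window) == 2L, window[1] <= window[2])
  sel <- which(trials$onsets >= window[1] & trials$onsets <= window[2])
  if (!length(sel)) {
    stop(sprintf("window [%g, %g] s captures no timepoints (onsets: %s)",
                 window[1], window[2],
                 paste(trials$onsets, collapse = ", ")), call. = FALSE)
  }
  resp <- trials$responses[, , sel, , drop = FALSE]
  # mean over repetitions and selected timepoints, ignoring dropped trials
  pat <- apply(resp, c(1, 4), mean, na.rm = TRUE)
  n_avail <- rowSums(apply(!is.na(resp), c(1, 2), all))
  structure(list(patterns = pat, roi = trials$roi, window = window,
                 timepoints_used = trials$onsets[sel],
                 repetitions_available = n_avail),
            class = "pattern_matrix")
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat(sprintf("pattern_matrix [%s]: %d scenes x %d voxels, window [%g, %g] s\n",
              x$roi, nrow(x$patterns), ncol(x$patterns),
              x$window[1], x$window[2]))
  invisible(x)
}

#' Average similarity matrices across participants
#'
#' Cell-wise mean of per-participant scene x scene similarity matrices
#' (averaging the raw r values, before any Fisher transformation; set
#' `fisher = TRUE` to average on the Fisher scale and back-transform).
#'
#' @param spaces list of [similarity_matrix()] objects of one dimension.
#' @param fisher average on the Fisher-z scale instead of raw r.
#' @return the group-average [similarity_matrix()].
#' @export
average_across_participants <- function(spaces, fisher = FALSE) {
  stopifnot(is.list(spaces), length(spaces) >= 1L)
  dims <- vapply(spaces, nrow, integer(1))
  if (length(unique(dims)) != 1L) {
    stop("all matrices must share one dimension", call. = FALSE)
  }
  mats <- lapply(spaces, function(m) matrix(as.numeric(m), nrow(m)))
  if (fisher) {
    avg <- fisher_z_inverse(Reduce(`+`, lapply(mats, fisher_z)) / length(mats))
  } else {
    avg <- Reduce(`+`, mats) / length(mats)
  }
  diag(avg) <- 1
  similarity_matrix(avg, method = attr(spaces[[1]], "method") %||% "group",
                    transform = "pearson")
}
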