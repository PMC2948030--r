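## Seed ROI geometry, validation and time-course extraction.

#' Construct a set of cubic seed ROIs
#'
#' Each ROI is a cube anchored at a centre voxel with a physical edge length;
#' the default 5 mm edge gives the conventional 125 mm^3 seed volume. The
#' edge is rounded to the nearest odd voxel count per axis, so on anisotropic
#' grids a "cube" may span different voxel counts per axis. A bilateral ROI
#' additionally includes the cube mirrored across the mid-sagittal (x) plane
#' and its time course averages both cubes.
#'
#' @param label Character vector of ROI names.
#' @param center Integer matrix (n x 3) of 1-based centre voxel coordinates.
#' @param edge_mm Cube edge length(s) in mm (default 5).
#' @param bilateral Logical vector (default `FALSE`).
#' @return A `roi_set` data frame.
#' @export
roi_set <- function(label, center, edge_mm = 5, bilateral = FALSE) {
  center <- matrix(as.integer(center), ncol = 3)
  stop_if_not(length(label) == nrow(center), "label/center length mismatch",
              class = "fcparcel_value_error")
  stop_if_not(!anyDuplicated(label), "duplicate ROI labels",
              class = "fcparcel_value_error")
  out <- data.frame(label = as.character(label), cx = center[, 1],
                    cy = center[, 2], cz = center[, 3],
                    edge_mm = rep_len(edge_mm, length(label)),
                    bilateral = rep_len(as.logical(bilateral), length(label)),
                    stringsAsFactors = FALSE)
  class(out) <- c("roi_set", "data.frame")
  out
}

# nearest odd voxel count for a physical edge length (minimum 1)
odd_extent <- function(edge_mm, voxel_mm) {
  n <- edge_mm / voxel_mm
  max(1L, as.integer(2 * round((n - 1) / 2) + 1))
}

#' Voxel linear indices of one ROI cube
#'
#' @param roi One-row slice of a `roi_set`.
#' @param grid_shape Length-3 voxel counts.
#' @param voxel_size_mm Length-3 voxel sizes (mm).
#' @return Integer vector of linear voxel indices (bilateral cubes unioned).
#' @export
roi_voxels <- function(roi, grid_shape, voxel_size_mm) {
  half <- vapply(seq_len(3), function(ax)
    (odd_extent(roi$edge_mm, voxel_size_mm[ax]) - 1L) %/% 2L, integer(1))
  ctr <- c(roi$cx, roi$cy, roi$cz)
  rngs <- lapply(seq_len(3), function(ax) (ctr[ax] - half[ax]):(ctr[ax] + half[ax]))
  for (ax in seq_len(3))
    stop_if_not(min(rngs[[ax]]) >= 1 && max(rngs[[ax]]) <= grid_shape[ax],
                sprintf("ROI '%s' extends outside the grid", roi$label),
                class = "fcparcel_geometry_error")
  g <- as.matrix(expand.grid(rngs[[1]], rngs[[2]], rngs[[3]]))
  idx <- g[, 1] + (g[, 2] - 1L) * grid_shape[1] +
    (g[, 3] - 1L) * grid_shape[1] * grid_shape[2]
  if (isTRUE(roi$bilateral)) {
    gx <- grid_shape[1] + 1L - g[, 1]
    idx2 <- gx + (g[, 2] - 1L) * grid_shape[1] +
      (g[, 3] - 1L) * grid_shape[1] * grid_shape[2]
    idx <- union(idx, idx2)
  }
  sort(as.integer(idx))
}

#' Validate seed ROIs against subject gray-matter masks
#'
#' An ROI passes when the across-subject mean gray-matter coverage of its
#' voxels is at least `min_overlap` (inclusive; default 0.70). Also checks
#' that ROIs do not overlap each other.
#'
#' @param rois A [roi_set()].
#' @param gm_masks List of per-subject 3-D gray-matter masks.
#' @param voxel_size_mm Length-3 voxel sizes (mm).
#' @param min_overlap Minimum mean GM fraction (default 0.70).
#' @return Data frame with per-ROI `gm_fraction` and `pass`.
#' @export
validate_rois <- function(rois, gm_masks, voxel_size_mm, min_overlap = 0.70) {
  stop_if_not(length(gm_masks) >= 1, "need at least one GM mask",
              class = "fcparcel_value_error")
  grid_shape <- dim(gm_masks[[1]])
  vox <- lapply(seq_len(nrow(rois)), function(i)
    roi_voxels(rois[i, ], grid_shape, voxel_size_mm))
  if (nrow(rois) > 1) {
    all_idx <- unlist(vox)
    stop_if_not(!anyDuplicated(all_idx), "ROIs overlap each other",
                class = "fcparcel_geometry_error")
  }
  frac <- vapply(vox, function(v) {
    mean(vapply(gm_masks, function(m) mean(as.numeric(m)[v]), numeric(1)))
  }, numeric(1))
  data.frame(label = rois$label, gm_fraction = frac,
             pass = frac >= min_overlap, stringsAsFactors = FALSE)
}

#' Extract a seed ROI's mean time course
#'
#' Arithmetic mean over the ROI voxels that fall inside the brain mask, at
#' each time point.
#'
#' @param run A `bold_run`.
#' @param roi One-row slice of a `roi_set`.
#' @return Numeric vector of length `n_volumes`.
#' @export
extract_roi_timecourse <- function(run, roi) {
  d <- dim(run$data)
  idx <- roi_voxels(roi, d[1:3], run$voxel_size_mm)
  idx <- idx[as.logical(run$brain_mask)[idx]]
  stop_if_not(length(idx) > 0,
              sprintf("ROI '%s' has no voxels inside the brain mask",
                      roi$label),
              class = "fcparcel_empty_roi_error")
  Y <- matrix(run$data, prod(d[1:3]), d[4])
  colMeans(Y[idx, , drop = FALSE])
}

#' Default seed placement on a synthetic atlas
#'
#' Places one cubic seed per network at the target-band voxel where that
#' network's weight peaks, mimicking seeds drawn over the target region.
#'
#' @param atlas A `network_atlas`.
#' @param edge_mm Seed edge length in mm (default 5, i.e. 125 mm^3).
#' @return A [roi_set()] with one ROI per network label.
#' @export
default_roi_set <- function(atlas, edge_mm = 5) {
  d <- atlas$grid_shape
  centers <- t(vapply(atlas$weights, function(w) {
    wt <- w
    wt[!atlas$target_mask] <- -Inf
    i <- which.max(wt)
    c((i - 1L) %% d[1] + 1L,
      ((i - 1L) %/% d[1]) %% d[2] + 1L,
      (i - 1L) %/% (d[1] * d[2]) + 1L)
  }, numeric(3)))
  roi_set(atlas$labels, centers, edge_mm = edge_mm)
}

#' Read / write an ROI table
#'
#' Tab-separated columns `label cx cy cz edge_mm bilateral`; coordinates in
#' the file are 0-based voxel indices (converted to 1-based internally).
#'
#' @param path File path.
#' @return `read_rois`: a [roi_set()].
#' @export
read_rois <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("label", "cx", "cy", "cz", "edge_mm", "bilateral")
  stop_if_not(all(need %in% names(tab)),
              sprintf("ROI file must have columns: %s",
                      paste(need, collapse = ", ")),
              class = "fcparcel_io_error")
  roi_set(tab$label, cbind(tab$cx, tab$cy, tab$cz) + 1L,
          edge_mm = tab$edge_mm, bilateral = as.logical(tab$bilateral))
}

#' @rdname read_rois
#' @param rois A [roi_set()] to write.
#' @export
write_rois <- function(rois, path) {
  out <- data.frame(label = rois$label, cx = rois$cx - 1L, cy = rois$cy - 1L,
                    cz = rois$cz - 1L, edge_mm = rois$edge_mm,
                    bilateral = rois$bilateral)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
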