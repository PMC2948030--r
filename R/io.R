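## NIfTI-1 and tabular I/O.

#' Write a 3-D or 4-D array as NIfTI-1
#'
#' @param map Numeric array (3-D map or 4-D time series).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Length-3 voxel sizes in mm.
#' @param tr_seconds Repetition time for 4-D data (optional).
#' @return The path, invisibly.
#' @export
write_map <- function(map, path, voxel_size_mm = c(1, 1, 1),
                      tr_seconds = NULL) {
  nd <- length(dim(map))
  stop_if_not(nd %in% c(3, 4), "expected a 3-D or 4-D array",
              class = "fcparcel_io_error")
  img <- RNifti::asNifti(map)
  pd <- if (nd == 4 && !is.null(tr_seconds)) c(voxel_size_mm, tr_seconds)
        else voxel_size_mm
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path NIfTI-1 file.
#' @param expect_dims Required dimensionality (3 or 4), or `NULL`.
#' @return Numeric array with `pixdim` attribute.
#' @export
read_map <- function(path, expect_dims = NULL) {
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (!is.null(expect_dims))
    stop_if_not(nd == expect_dims,
                sprintf("%s: expected %d-D image, found %d-D", path,
                        expect_dims, nd),
                class = "fcparcel_io_error")
  out <- array(as.numeric(img), dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

#' Assemble a BOLD run from files
#'
#' @param bold_path 4-D NIfTI BOLD file.
#' @param mask_paths Named list of 3-D NIfTI paths: `brain`, `gm`, `wm`,
#'   `csf`.
#' @param motion_path Whitespace-delimited 6-column motion table
#'   (3 translations mm, 3 rotations deg).
#' @param tr_seconds Repetition time; when `NULL`, taken from the NIfTI
#'   header.
#' @param subject_id,age,sex Subject metadata.
#' @return A `bold_run`.
#' @export
read_bold <- function(bold_path, mask_paths, motion_path, tr_seconds = NULL,
                      subject_id = "sub", age = NA_real_,
                      sex = NA_character_) {
  dat <- read_map(bold_path, expect_dims = 4)
  pd <- attr(dat, "pixdim")
  if (is.null(tr_seconds)) tr_seconds <- pd[4]
  masks <- lapply(mask_paths, function(p) {
    m <- read_map(p, expect_dims = 3)
    stop_if_not(identical(dim(m), dim(dat)[1:3]),
                sprintf("mask %s does not match the BOLD grid", p),
                class = "fcparcel_io_error")
    array(m > 0, dim(m))
  })
  for (nm in c("brain", "gm", "wm", "csf"))
    stop_if_not(!is.null(masks[[nm]]), sprintf("mask '%s' missing", nm),
                class = "fcparcel_io_error")
  motion <- as.matrix(utils::read.table(motion_path))
  stop_if_not(ncol(motion) == 6 && nrow(motion) == dim(dat)[4],
              "motion table must be n_volumes x 6",
              class = "fcparcel_io_error")
  structure(list(data = array(as.numeric(dat), dim(dat)),
                 tr_seconds = tr_seconds, voxel_size_mm = pd[1:3],
                 brain_mask = masks$brain, gm_mask = masks$gm,
                 wm_mask = masks$wm, csf_mask = masks$csf,
                 motion = unname(motion), subject_id = subject_id,
                 age = age, sex = sex),
            class = "bold_run")
}

#' Write a simulated cohort to disk
#'
#' Per subject: 4-D BOLD (`.nii.gz`), motion table; shared: masks, network
#' weights, target mask, and a JSON ground-truth manifest.
#'
#' @param runs List of `bold_run`.
#' @param atlas The `network_atlas`.
#' @param truth The `ground_truth`.
#' @param cfg The `sim_config`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(runs, atlas, truth, cfg, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  stop_if_not(ok, sprintf("cannot create output directory %s", dir),
              class = "fcparcel_io_error")
  vs <- atlas$voxel_size_mm
  for (r in runs) {
    write_map(r$data, file.path(dir, paste0(r$subject_id, "_bold.nii.gz")),
              vs, r$tr_seconds)
    utils::write.table(r$motion,
                       file.path(dir, paste0(r$subject_id, "_motion.txt")),
                       row.names = FALSE, col.names = FALSE)
  }
  for (nm in c("brain_mask", "gm_mask", "wm_mask", "csf_mask",
               "target_mask"))
    write_map(array(as.numeric(atlas[[nm]]), atlas$grid_shape),
              file.path(dir, paste0(nm, ".nii.gz")), vs)
  for (k in seq_along(atlas$weights))
    write_map(atlas$weights[[k]],
              file.path(dir, paste0("weight_", atlas$labels[k], ".nii.gz")),
              vs)
  manifest <- list(
    config = unclass(cfg),
    labels = atlas$labels,
    anticorrelated_pair = atlas$anticorrelated_pair,
    anticorrelation = truth$anticorrelation,
    subject_seeds = truth$subject_seeds,
    subjects = data.frame(id = vapply(runs, `[[`, "", "subject_id"),
                          age = vapply(runs, `[[`, 0, "age"),
                          sex = vapply(runs, `[[`, "", "sex")))
  jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(truth$network_timecourses,
                     file.path(dir, "network_timecourses.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
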