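## Cohort-level workflows and the end-to-end pipeline orchestrator.

#' Seed-connectivity analysis of a cohort
#'
#' Preprocesses every run (smoothed branch), fits the joint prewhitened
#' seed GLM per subject, calibrates the cluster-extent threshold once by
#' Monte-Carlo simulation on the shared brain mask, thresholds each
#' subject's t maps, and builds per-seed group random-effects maps and
#' positive-cluster probability maps.
#'
#' @param runs List of `bold_run` (raw).
#' @param rois A [roi_set()].
#' @param fwhm_mm Smoothing FWHM (default 8 mm).
#' @param band_hz Temporal pass band (default `c(0.01, 0.1)` Hz).
#' @param voxel_p Voxelwise two-tailed threshold (default 0.01).
#' @param alpha Cluster-level alpha (default 0.05).
#' @param mc_iters Monte-Carlo iterations (default 1000).
#' @param nuisance_mode Passed to [build_nuisance()].
#' @param seed Integer seed (Monte-Carlo calibration).
#' @return List: `subject_maps` (per subject, per seed `stat_map` with
#'   cluster labels), `K`, `group` (per-seed group `stat_map`),
#'   `prob_maps` (per-seed percent maps of positive supra-threshold
#'   clusters), `roi_validation`.
#' @export
seedfc_cohort <- function(runs, rois, fwhm_mm = 8, band_hz = c(0.01, 0.1),
                          voxel_p = 0.01, alpha = 0.05, mc_iters = 1000,
                          nuisance_mode = "expanded", seed = 1L) {
  gm_masks <- lapply(runs, `[[`, "gm_mask")
  val <- validate_rois(rois, gm_masks, runs[[1]]$voxel_size_mm)
  pre <- lapply(runs, preprocess_run, fwhm_mm = fwhm_mm, band_hz = band_hz,
                smooth = TRUE)
  subject_maps <- lapply(pre, seed_fc_map, rois = rois,
                         nuisance_mode = nuisance_mode)
  K <- monte_carlo_cluster_threshold(runs[[1]]$brain_mask, fwhm_mm,
                                     runs[[1]]$voxel_size_mm,
                                     voxel_p = voxel_p, alpha = alpha,
                                     n_iter = mc_iters, seed = seed)
  subject_maps <- lapply(subject_maps, function(per_seed)
    lapply(per_seed, threshold_clusters, voxel_p = voxel_p, K = K))
  ages <- vapply(runs, `[[`, 0, "age")
  sexes <- vapply(runs, `[[`, "", "sex")
  seed_names <- rois$label
  group <- NULL
  if (length(runs) >= 3 && !anyNA(ages) && !anyNA(sexes) &&
      length(unique(sexes)) == 2) {
    group <- lapply(seed_names, function(sn)
      group_random_effects(lapply(subject_maps, function(sm) sm[[sn]]$beta),
                           ages, sexes, mask = runs[[1]]$brain_mask))
    names(group) <- seed_names
  }
  prob_maps <- lapply(seed_names, function(sn)
    probability_map(lapply(subject_maps, function(sm)
      array(sm[[sn]]$labels > 0, dim(sm[[sn]]$labels)))))
  names(prob_maps) <- seed_names
  list(subject_maps = subject_maps, K = as.integer(K), group = group,
       prob_maps = prob_maps, roi_validation = val,
       params = list(fwhm_mm = fwhm_mm, band_hz = band_hz,
                     voxel_p = voxel_p, alpha = alpha, mc_iters = mc_iters,
                     nuisance_mode = nuisance_mode, seed = seed))
}

#' Voxelwise fuzzy parcellation of a cohort's target region
#'
#' Runs the unsmoothed branch: temporal filtering only, per-subject PCA
#' reduction of target-region voxel time courses, fuzzy c-means (with
#' unsupervised cluster-count selection when `c = "auto"`: the modal
#' Xie-Beni optimum across subjects), exact Dice-based cluster alignment
#' across subjects with two consensus passes, and group probabilistic
#' cluster maps.
#'
#' @param runs List of `bold_run` (raw).
#' @param target_mask 3-D mask of the region to parcellate.
#' @param c Cluster count, or `"auto"` (default).
#' @param m Fuzziness exponent (default 1.3).
#' @param c_range Candidate counts for the unsupervised search
#'   (default `2:8`).
#' @param restarts Restarts per candidate (default 10).
#' @param var_frac PCA variance fraction retained (default 0.90).
#' @param band_hz Temporal pass band (default `c(0.01, 0.1)` Hz).
#' @param seed Integer seed.
#' @return List: `c_star`, `per_subject_c`, `partitions`, `aligned`,
#'   `prob_maps` (class `cluster_prob_maps`), `consensus_map`,
#'   `voxel_idx`, `index_tables`.
#' @export
parcellate_cohort <- function(runs, target_mask, c = "auto", m = 1.3,
                              c_range = 2:8, restarts = 10, var_frac = 0.90,
                              band_hz = c(0.01, 0.1), seed = 42L) {
  d <- dim(runs[[1]]$data)[1:3]
  voxel_idx <- which(as.logical(target_mask))
  stop_if_not(length(voxel_idx) >= 2, "target mask has fewer than 2 voxels",
              class = "fcparcel_mask_error")
  pre <- lapply(runs, preprocess_run, fwhm_mm = 0, band_hz = band_hz,
                smooth = FALSE)
  Xs <- lapply(pre, function(r) {
    Y <- matrix(r$data, prod(d), dim(r$data)[4])
    Y[voxel_idx, , drop = FALSE]
  })
  reduced <- lapply(Xs, pca_reduce, var_frac = var_frac)
  index_tables <- NULL
  per_subject_c <- NULL
  if (identical(c, "auto")) {
    sel <- lapply(seq_along(reduced), function(i)
      select_n_clusters(reduced[[i]]$scores, c_range = c_range, m = m,
                        restarts = restarts, seed = child_seed(seed, i)))
    per_subject_c <- vapply(sel, `[[`, 0L, "c_star")
    index_tables <- lapply(sel, `[[`, "index_table")
    tabc <- table(per_subject_c)
    c <- as.integer(names(tabc)[which.max(tabc)])
  }
  c <- as.integer(c)
  partitions <- lapply(seq_along(reduced), function(i)
    fcm(reduced[[i]]$scores, c, m = m, seed = child_seed(seed, 10000 + i)))
  hard <- lapply(partitions, harden)
  mt <- match_clusters(hard, c)
  prob <- cluster_probability_maps(mt$aligned, c, voxel_idx, d)
  list(c_star = c, per_subject_c = per_subject_c, partitions = partitions,
       aligned = mt$aligned, permutations = mt$permutations,
       prob_maps = prob,
       consensus_map = labels_to_map(mt$consensus, voxel_idx, d),
       voxel_idx = voxel_idx, index_tables = index_tables,
       params = list(m = m, c_range = c_range, restarts = restarts,
                     var_frac = var_frac, seed = seed))
}

#' Pipeline configuration
#'
#' Validated bundle of every stage's parameters. Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    n_subjects = 16L, n_volumes = 200L, tr_seconds = 2, snr = 1,
    noise_ar1 = 0.3, grid_shape = c(24L, 24L, 18L),
    voxel_size_mm = c(4, 4, 5),
    fwhm_mm = 8, band_hz = c(0.01, 0.1),
    voxel_p = 0.01, alpha = 0.05, mc_iters = 1000,
    nuisance_mode = "expanded",
    parcel_c = "auto", parcel_m = 1.3, c_range = c(2L, 8L), restarts = 10L,
    n_splits = 100L, reliability_mode = "fuzzy",
    seed = 42L, output_dir = NULL)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  stop_if_not(length(unknown) == 0,
              sprintf("unknown config key(s): %s",
                      paste(unknown, collapse = ", ")),
              class = "fcparcel_config_error")
  cfg <- utils::modifyList(defaults, ov)
  # validate numeric ranges up front, before any compute
  sim_config(cfg$n_subjects, cfg$n_volumes, cfg$tr_seconds, cfg$band_hz,
             cfg$snr, cfg$noise_ar1, seed = cfg$seed)
  stop_if_not(cfg$fwhm_mm >= 0, "fwhm_mm must be nonnegative",
              class = "fcparcel_config_error")
  stop_if_not(cfg$voxel_p > 0 && cfg$voxel_p < 1 &&
                cfg$alpha > 0 && cfg$alpha <= 1,
              "voxel_p/alpha must be probabilities",
              class = "fcparcel_config_error")
  stop_if_not(cfg$parcel_m > 1, "parcel_m must be > 1",
              class = "fcparcel_config_error")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulate -> preprocess -> seed connectivity (with Monte-Carlo cluster
#' correction, group maps, probability maps) -> fuzzy parcellation ->
#' split-half reliability. Deterministic given the config seed. When
#' `config$output_dir` is set, maps and a JSON manifest recording every
#' parameter are written there.
#'
#' @param config A [pipeline_config()].
#' @return List with `cohort`, `seedfc`, `parcellation`, `reliability`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(errorCondition(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)),
                          class = c("fcparcel_stage_error", "error",
                                    "condition"))))
  }
  message("fuzziness convention: exponent m = ", config$parcel_m,
          " (> 1 scale); nuisance mode: ", config$nuisance_mode,
          " (3 sources x course/derivative/square)")
  cfg <- sim_config(config$n_subjects, config$n_volumes, config$tr_seconds,
                    config$band_hz, config$snr, config$noise_ar1,
                    seed = config$seed)
  atlas <- stage("atlas", make_default_atlas(config$grid_shape,
                                             config$voxel_size_mm,
                                             seed = config$seed))
  cohort <- stage("simulate", simulate_cohort(cfg, atlas))
  rois <- default_roi_set(atlas)
  sfc <- stage("seedfc", seedfc_cohort(cohort$runs, rois,
                                       fwhm_mm = config$fwhm_mm,
                                       band_hz = config$band_hz,
                                       voxel_p = config$voxel_p,
                                       alpha = config$alpha,
                                       mc_iters = config$mc_iters,
                                       nuisance_mode = config$nuisance_mode,
                                       seed = config$seed))
  parc <- stage("parcellate",
                parcellate_cohort(cohort$runs, atlas$target_mask,
                                  c = config$parcel_c, m = config$parcel_m,
                                  c_range = config$c_range[1]:config$c_range[2],
                                  restarts = config$restarts,
                                  band_hz = config$band_hz,
                                  seed = config$seed))
  # reliability of the per-seed binary supra-threshold maps via
  # probability-map overlap
  map_sets <- lapply(rois$label, function(sn)
    lapply(sfc$subject_maps, function(sm)
      array(sm[[sn]]$labels > 0, dim(sm[[sn]]$labels))))
  names(map_sets) <- rois$label
  builder <- function(maps) probability_map(maps) / 100
  rel <- stage("reliability",
               split_half(map_sets, builder, n_splits = config$n_splits,
                          seed = child_seed(config$seed, 77),
                          mode = config$reliability_mode))
  manifest <- list(config = unclass(config),
                   K = sfc$K,
                   c_star = parc$c_star,
                   mean_r_sb = attr(rel, "summary")$mean_r_sb,
                   assumptions = c(
                     "nuisance covariates: 3 sources expanded to course + derivative + square",
                     sprintf("fuzziness exponent m = %g on the standard (> 1) scale",
                             config$parcel_m)))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    vs <- config$voxel_size_mm
    for (sn in rois$label) {
      write_map(sfc$prob_maps[[sn]],
                file.path(config$output_dir,
                          sprintf("probmap_%s.nii.gz", sn)), vs)
      if (!is.null(sfc$group))
        write_map(sfc$group[[sn]]$t_values,
                  file.path(config$output_dir,
                            sprintf("group_t_%s.nii.gz", sn)), vs)
    }
    for (k in seq_along(parc$prob_maps))
      write_map(parc$prob_maps[[k]],
                file.path(config$output_dir,
                          sprintf("cluster_prob_%d.nii.gz", k)), vs)
    write_map(parc$consensus_map,
              file.path(config$output_dir, "consensus_labels.nii.gz"), vs)
    utils::write.table(as.data.frame(rel),
                       file.path(config$output_dir, "reliability.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(cohort = cohort, seedfc = sfc, parcellation = parc,
       reliability = rel, manifest = manifest)
}
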