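# fcparcel

Seed-based functional connectivity and fuzzy connectivity-based
parcellation for resting-state BOLD fMRI, in R.

## What this package is for

Resting-state functional connectivity (rsFC) maps the temporal correlation
of spontaneous low-frequency BOLD fluctuations. A standard study design
asks two questions about a cortical target region:

1. **Seed mapping** — for small seed regions of interest (ROIs) placed
   over the target, which voxels across the brain correlate (positively or
   negatively) with each seed's time course, after removing nuisance
   signals?
2. **Parcellation** — do the target's voxels fall into distinct clusters
   by their connectivity fingerprints, and do those clusters align with
   known large-scale networks (e.g. the anticorrelated task-positive and
   task-negative/default-mode networks)?

`fcparcel` implements both branches as a tested, reproducible pipeline,
plus the reliability analysis that quantifies how stable the resulting
group maps are across subject subsets. Because public resting-state
datasets are large and the original acquisitions are rarely shareable, the
package ships a synthetic cohort generator that plants known network
structure — so every stage can be validated against ground truth.

## The methods at its core

* **Preprocessing** — per-voxel linear detrending, zero-phase Butterworth
  band-pass (0.01–0.1 Hz), Gaussian smoothing (8 mm FWHM,
  mask-renormalized; the parcellation branch runs unsmoothed).
* **Seed GLM** — seed time courses are averaged over 125 mm³ cubic ROIs
  validated against ≥ 70 % gray-matter coverage, residualized on the
  nuisance set, z-normalized and sequentially orthogonalized; the voxelwise
  model includes 9 tissue/global nuisance covariates (white matter, CSF and
  global courses, each with its temporal derivative and square) and 6
  motion parameters, with per-voxel AR(1) prewhitening
  (Cochrane–Orcutt). Each seed yields a t map (SPM-t).
* **Cluster-extent correction** — the minimum cluster size K at a given
  voxelwise p and family-wise alpha is calibrated by Monte-Carlo
  simulation of smoothed Gaussian noise on the analysis mask
  (6-connectivity).
* **Group maps** — random-effects GLM of subject betas controlling for age
  and sex; probability maps as the percentage of subjects supra-threshold.
* **Parcellation** — per-subject PCA of target-voxel time courses
  (retaining ≥ 90 % variance), fuzzy c-means with memberships
  `u_ik = 1 / Σ_j (d_ik/d_jk)^(2/(m−1))`, unsupervised cluster-count
  selection by the Xie–Beni index over c ∈ [2, 8] with multiple restarts,
  exact Dice-based cluster alignment across subjects, and probabilistic
  cluster maps (reported in the 10–100 % interval).
* **Reliability** — random equal splits of the cohort; Sørensen–Dice
  overlap `r_h = 2C/(A+B)` (fuzzy variant `2 Σ min(a,b)/(Σa+Σb)`) between
  the two half-cohort group maps, projected to full-sample reliability by
  Spearman–Brown `R_SB = 2 r_h / (1 + r_h)`.

## Worked example

```r
library(fcparcel)

atlas  <- make_default_atlas()              # 24 x 24 x 18 grid, 4 networks
cfg    <- sim_config(n_subjects = 16, seed = 42)
cohort <- simulate_cohort(cfg, atlas)
rois   <- default_roi_set(atlas)            # one 125 mm^3 seed per network

# seed branch: smoothed, prewhitened joint GLM, Monte-Carlo K, group maps
sfc <- seedfc_cohort(cohort$runs, rois, mc_iters = 1000, seed = 42)
sfc$K
#> [1] 12

# parcellation branch: unsmoothed, PCA + fuzzy c-means, auto cluster count
parc <- parcellate_cohort(cohort$runs, atlas$target_mask, c = "auto",
                          seed = 42)
parc$c_star
#> [1] 4
table(parc$per_subject_c)
#> 4
#> 16

# split-half reliability of the per-seed probability maps
sets <- lapply(rois$label, function(sn)
  lapply(sfc$subject_maps, function(sm)
    array(sm[[sn]]$labels > 0, dim(sm[[sn]]$labels))))
names(sets) <- rois$label
rel <- split_half(sets, function(m) probability_map(m) / 100,
                  n_splits = 50, seed = 7)
attr(rel, "summary")$mean_r_sb
#> [1] 0.952552
```

Reading the output: the Monte-Carlo calibration says clusters below 12
voxels are discarded at p < 0.05 family-wise; the unsupervised search
recovers the four planted networks in every subject; and the group
probability maps are highly stable across random half-cohorts (mean
Spearman–Brown reliability ≈ 0.95, far above the 0.60 convention for
"good" reliability). `run_pipeline(pipeline_config())` chains all of the
above and writes NIfTI maps plus a JSON manifest.

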