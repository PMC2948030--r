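# Cohort generator: planted structure, band confinement, reproducibility.

test_that("default atlas satisfies its structural invariants", {
  atlas <- make_default_atlas(c(16, 16, 16), seed = 1)
  expect_length(atlas$weights, 4)
  for (w in atlas$weights) {
    expect_identical(dim(w), atlas$grid_shape)
    expect_true(all(w >= 0 & w <= 1))
    expect_true(any(w > 0.5))
  }
  expect_true(all(!(atlas$weights$TPN > 0 & atlas$weights$TNN > 0)))
  n_hit <- sum(vapply(atlas$weights, function(w)
    any(w[atlas$target_mask] > 0), logical(1)))
  expect_gte(n_hit, 2)
  expect_true(all(atlas$gm_mask <= atlas$brain_mask))
  expect_true(all(atlas$target_mask <= atlas$gm_mask))
})

test_that("atlas layout is deterministic given the grid", {
  a1 <- make_default_atlas(c(16, 16, 16), seed = 1)
  a2 <- make_default_atlas(c(16, 16, 16), seed = 2)
  for (k in 1:4) expect_identical(a1$weights[[k]], a2$weights[[k]])
  expect_identical(a1$target_mask, a2$target_mask)
})

test_that("too-small grids raise a sizing error", {
  expect_error(make_default_atlas(c(4, 4, 4)), class = "fcparcel_sizing_error")
})

test_that("network time courses are unit variance, anticorrelated and band-limited", {
  atlas <- tiny_atlas()
  cfg <- sim_config(n_subjects = 1, n_volumes = 200, seed = 7)
  truth <- simulate_network_timecourses(cfg, atlas)
  C <- truth$network_timecourses
  expect_identical(colnames(C), atlas$labels)
  for (k in 1:4) expect_equal(var(C[, k]), 1, tolerance = 0.05)
  R <- cor(C)
  expect_lte(R["TPN", "TNN"], -0.5)
  off <- abs(R[upper.tri(R)])
  expect_true(all(off[off < 0.5] <= 0.3)) # all non-pair correlations small
  for (k in 1:4)
    expect_gte(band_power_fraction(C[, k], cfg$tr_seconds, 0.01, 0.1), 0.9)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_volumes = 16), class = "fcparcel_config_error")
  expect_error(sim_config(band_hz = c(0.05, 0.3)),
               class = "fcparcel_config_error") # above Nyquist for TR 2
  expect_error(sim_config(snr = 0), class = "fcparcel_config_error")
})

test_that("planted voxels recover their network course, more strongly at high snr", {
  atlas <- tiny_atlas()
  planted <- which(atlas$weights$TPN > 0.95 & atlas$weights$TNN == 0 &
                     atlas$weights$MOT == 0 & atlas$weights$VIS == 0)
  expect_gt(length(planted), 0)
  mean_corr <- function(snr) {
    cfg <- tiny_cfg(n_subjects = 1, n_volumes = 100, snr = snr, seed = 13)
    truth <- simulate_network_timecourses(cfg, atlas)
    run <- simulate_subject(cfg, atlas, truth, 1)
    Y <- matrix(run$data, prod(atlas$grid_shape), cfg$n_volumes)
    mean(vapply(planted, function(i)
      cor(detrend_linear(Y[i, ]),
          detrend_linear(truth$network_timecourses[, "TPN"])),
      numeric(1)))
  }
  r <- vapply(c(0.25, 0.5, 1, 2), mean_corr, numeric(1))
  expect_true(all(diff(r) > 0)) # monotone recoverability
  expect_gte(r[3], 0.5)         # snr = 1 average
  expect_gte(mean_corr(1e6), 0.999) # noiseless limit
})

test_that("subjects share planted weights but differ in noise; cohorts reproduce bit-identically", {
  co <- tiny_cohort()
  expect_length(co$runs, 2)
  expect_false(identical(co$runs[[1]]$data, co$runs[[2]]$data))
  expect_identical(co$runs[[1]]$brain_mask, co$runs[[2]]$brain_mask)
  co2 <- simulate_cohort(tiny_cfg(), tiny_atlas())
  expect_identical(co$runs[[1]]$data, co2$runs[[1]]$data)
  expect_identical(co$runs[[2]]$motion, co2$runs[[2]]$motion)
  expect_identical(co$truth$network_timecourses,
                   co2$truth$network_timecourses)
})

test_that("motion parameters stay within the 1 mm / 1 degree exclusion limit", {
  co <- tiny_cohort()
  for (r in co$runs) expect_lte(max(abs(r$motion)), 1)
})
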