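# Sorensen overlap, Spearman-Brown correction, split-half reliability.

test_that("Sorensen index matches its closed forms", {
  d <- c(6, 6, 2)
  a <- array(0, d); a[1:10] <- 1
  expect_equal(sorensen(a, a, "binary"), 1)
  b <- array(0, d); b[11:20] <- 1
  expect_equal(sorensen(a, b, "binary"), 0)
  # A = 10, B = 10, C = 5 -> 0.5
  c5 <- array(0, d); c5[6:15] <- 1
  expect_equal(sorensen(a, c5, "binary"), 0.5)
})

test_that("fuzzy Sorensen reduces to binary on 0/1 maps and validates inputs", {
  set.seed(60)
  d <- c(5, 5, 4)
  a <- array(rbinom(prod(d), 1, 0.4), d)
  b <- array(rbinom(prod(d), 1, 0.4), d)
  expect_equal(sorensen(a, b, "fuzzy"), sorensen(a, b, "binary"))
  fa <- array(runif(prod(d)), d)
  expect_error(sorensen(fa * 2, fa, "fuzzy"), class = "fcparcel_value_error")
  expect_error(sorensen(fa, fa, "binary"), class = "fcparcel_value_error")
  expect_error(sorensen(a, array(0, c(4, 4, 4))),
               class = "fcparcel_grid_error")
  z <- array(0, d)
  expect_warning(r <- sorensen(z, z, "binary"), "empty")
  expect_equal(r, 1)
})

test_that("Spearman-Brown formula is exact and monotone", {
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0.5), 2 / 3)
  r <- seq(0, 1, by = 0.01)
  expect_true(all(diff(spearman_brown(r)) > 0))
  expect_true(all(spearman_brown(r) >= r))
  expect_error(spearman_brown(1.2), class = "fcparcel_value_error")
})

test_that("identical subject maps give r_sb = 1 on every split", {
  d <- c(6, 6, 4)
  m <- array(0, d); m[2:4, 2:4, 2] <- 1
  rep_ <- split_half(rep(list(m), 8), function(maps)
    probability_map(maps) / 100, n_splits = 10, seed = 61)
  expect_true(all(rep_$r_sb == 1))
})

test_that("split-half of independent random maps matches a simulation oracle", {
  set.seed(62)
  d <- c(8, 8, 6)
  maps <- lapply(1:12, function(i) array(rbinom(prod(d), 1, 0.5), d))
  builder <- function(ms) probability_map(ms) / 100
  rep_ <- split_half(maps, builder, n_splits = 40, seed = 63)
  # oracle: direct simulation with its own RNG, no split_half machinery
  oracle <- mean(replicate(60, {
    mm <- lapply(1:12, function(i) array(rbinom(prod(d), 1, 0.5), d))
    h1 <- Reduce(`+`, mm[1:6]) / 6
    h2 <- Reduce(`+`, mm[7:12]) / 6
    rh <- 2 * sum(pmin(h1, h2)) / (sum(h1) + sum(h2))
    2 * rh / (1 + rh)
  }))
  expect_equal(attr(rep_, "summary")$mean_r_sb, oracle, tolerance = 0.05)
})

test_that("split-half validates subject counts", {
  d <- c(4, 4, 2)
  maps <- lapply(1:5, function(i) array(rbinom(32, 1, 0.5), d))
  expect_error(split_half(maps, identity, 5), class = "fcparcel_value_error")
  expect_error(split_half(maps[1:2], identity, 5),
               class = "fcparcel_value_error")
})

test_that("reliability grows with the planted signal-to-noise ratio", {
  atlas <- tiny_atlas()
  rois <- default_roi_set(atlas)
  rel_at_snr <- function(snr) {
    cfg <- sim_config(n_subjects = 8, n_volumes = 100, snr = snr, seed = 64)
    co <- simulate_cohort(cfg, atlas)
    sfc <- seedfc_cohort(co$runs, rois, mc_iters = 100, seed = 64)
    sets <- lapply(rois$label, function(sn)
      lapply(sfc$subject_maps, function(sm)
        array(sm[[sn]]$labels > 0, dim(sm[[sn]]$labels))))
    names(sets) <- rois$label
    rep_ <- split_half(sets, function(ms) probability_map(ms) / 100,
                       n_splits = 15, seed = 65)
    attr(rep_, "summary")$mean_r_sb
  }
  r <- vapply(c(0.25, 1, 4), rel_at_snr, numeric(1))
  expect_true(all(diff(r) > 0))
})
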