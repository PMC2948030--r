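# Nuisance assembly, orthogonalization, prewhitening, GLM fitting, seed maps.

test_that("nuisance design has 9 tissue/global + 6 motion columns, all centered", {
  run <- handmade_run()
  X <- build_nuisance(run)
  expect_identical(ncol(X), 15L)
  expect_identical(sum(attr(X, "roles") == "nuisance_tissue"), 9L)
  expect_identical(sum(attr(X, "roles") == "motion"), 6L)
  expect_lt(max(abs(colMeans(X))), 1e-10)
  expect_identical(ncol(build_nuisance(run, mode = "plain")), 9L) # 3 + 6
})

test_that("the global column recovers an injected global course", {
  g <- as.numeric(bandpass(rnorm(80), 2, 0.01, 0.1)) * 3
  run <- handmade_run(global_course = g)
  X <- build_nuisance(run)
  expect_gte(cor(X[, "global"], g), 0.9)
})

test_that("zero-variance motion columns are dropped with a warning", {
  run <- handmade_run()
  run$motion[] <- 0
  expect_warning(X <- build_nuisance(run), "zero-variance motion")
  expect_identical(ncol(X), 9L)
})

test_that("empty tissue masks raise a mask error", {
  run <- handmade_run()
  run$wm_mask[] <- FALSE
  expect_error(build_nuisance(run), class = "fcparcel_mask_error")
})

test_that("seed orthogonalization yields an orthonormal set in ROI order", {
  set.seed(10)
  s <- lapply(1:3, function(i) rnorm(100))
  o <- orthogonalize_seeds(s)
  M <- do.call(cbind, o)
  G <- crossprod(M) / 99
  expect_equal(G, diag(3), tolerance = 1e-6,
               ignore_attr = TRUE) # QR-style orthonormality
  expect_lt(max(abs(crossprod(M) - diag(diag(crossprod(M))))), 1e-8)
  # first series is only z-normalized
  expect_equal(o[[1]], (s[[1]] - mean(s[[1]])) / sd(s[[1]]))
  # already-orthogonal inputs unchanged up to z-normalization
  q <- qr.Q(qr(matrix(rnorm(200), 100)))
  o2 <- orthogonalize_seeds(list(q[, 1], q[, 2]))
  expect_gt(abs(cor(o2[[2]], q[, 2])), 0.999)
})

test_that("duplicated seeds raise a collinearity error naming the ROI", {
  x <- rnorm(50)
  err <- tryCatch(orthogonalize_seeds(list(a = x, b = x)),
                  error = function(e) e)
  expect_s3_class(err, "fcparcel_collinearity_error")
  expect_match(conditionMessage(err), "b")
})

test_that("orthogonalization is order dependent only beyond the first seed", {
  set.seed(11)
  a <- rnorm(80); b <- a + rnorm(80)
  o1 <- orthogonalize_seeds(list(a = a, b = b))
  o2 <- orthogonalize_seeds(list(b = b, a = a))
  expect_equal(o1$a, (a - mean(a)) / sd(a))
  expect_equal(o2$b, (b - mean(b)) / sd(b))
  expect_false(isTRUE(all.equal(o1$b, o2$b[order(seq_along(b))])))
})

test_that("AR(1) estimation is calibrated on white and AR(1) noise", {
  X <- cbind(1, seq_len(200) / 200)
  set.seed(12)
  rhos_white <- replicate(20, prewhiten(rnorm(200), X)$rho)
  expect_lt(max(abs(rhos_white)), 0.15)
  rhos_ar <- replicate(20, {
    y <- as.numeric(arima.sim(list(ar = 0.5), 200))
    prewhiten(y, X)$rho
  })
  expect_lt(max(abs(rhos_ar - 0.5)), 0.15)
  # residual lag-1 autocorrelation after quasi-differencing is small
  set.seed(13)
  y <- as.numeric(arima.sim(list(ar = 0.5), 200))
  pw <- prewhiten(y, X)
  r2 <- lm.fit(pw$X, pw$y)$residuals
  expect_lt(abs(sum(r2[-1] * r2[-length(r2)]) / sum(r2^2)), 0.1)
})

test_that("rho = 0 leaves the model untouched; extreme rho is clipped", {
  X <- cbind(1, rnorm(50))
  y <- X %*% c(1, 2) # exact fit -> zero residuals -> rho 0
  pw <- prewhiten(as.numeric(y), X)
  expect_identical(pw$rho, 0)
  expect_identical(pw$X, X)
  # a pure ramp against an intercept-only design leaves residuals with
  # lag-1 autocorrelation ~ 1, which must be clipped
  expect_warning(pw2 <- prewhiten(as.numeric(1:300), cbind(rep(1, 300))),
                 "clipped")
  expect_equal(abs(pw2$rho), 0.95)
})

test_that("fit_glm matches the normal-equations oracle", {
  set.seed(15)
  X <- cbind(1, matrix(rnorm(300), 100))
  y <- rnorm(100)
  f <- fit_glm(y, X)
  beta_or <- solve(t(X) %*% X) %*% t(X) %*% y
  expect_equal(f$beta, as.numeric(beta_or), tolerance = 1e-8)
  res <- y - X %*% beta_or
  se_or <- sqrt(drop(crossprod(res)) / (100 - 4) *
                  diag(solve(crossprod(X))))
  expect_equal(f$t, as.numeric(beta_or) / se_or, tolerance = 1e-8)
  expect_identical(f$dof, 96L)
})

test_that("exact fits are capped and flagged; rank deficiency is reported", {
  x <- rnorm(30)
  f <- fit_glm(2 * x, cbind(x))
  expect_equal(f$beta, 2, tolerance = 1e-10)
  expect_true(f$exact_fit)
  expect_equal(abs(f$t), 1e6)
  X <- cbind(a = 1, b = x, c = x)
  err <- tryCatch(fit_glm(rnorm(30), X), error = function(e) e)
  expect_s3_class(err, "fcparcel_rank_error")
  expect_match(conditionMessage(err), "c")
})

test_that("GLM type-I error is nominal under the null", {
  set.seed(16)
  n <- 60
  X <- cbind(1, rnorm(n))
  p <- replicate(1000, {
    f <- fit_glm(rnorm(n), X)
    2 * pt(-abs(f$t[2]), f$dof)
  })
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("seed FC maps show planted positive and anticorrelated negative t", {
  co <- tiny_cohort()
  atlas <- tiny_atlas()
  pre <- preprocess_run(co$runs[[1]])
  rois <- default_roi_set(atlas)
  maps <- seed_fc_map(pre, rois)
  for (k in seq_along(maps)) {
    sup <- atlas$weights[[k]] > 0.5
    expect_gt(mean(maps[[k]]$t_values[sup]), 2)
  }
  expect_lt(mean(maps$TPN$t_values[atlas$weights$TNN > 0.5]), 0)
  expect_lt(mean(maps$TNN$t_values[atlas$weights$TPN > 0.5]), 0)
})

test_that("non-orthogonalized seed maps agree with orthogonalized ones", {
  co <- tiny_cohort()
  atlas <- tiny_atlas()
  pre <- preprocess_run(co$runs[[1]])
  rois <- default_roi_set(atlas)
  m1 <- seed_fc_map(pre, rois)
  m2 <- seed_fc_map(pre, rois, orthogonalize = FALSE)
  # rank correlation: robust to the capped exact-fit voxels inside each
  # seed cube, which dominate a Pearson comparison
  msk <- as.logical(atlas$brain_mask)
  for (k in seq_along(m1))
    expect_gt(cor(m1[[k]]$t_values[msk], m2[[k]]$t_values[msk],
                  method = "spearman"), 0.7)
})

test_that("constant seed regressors are rejected", {
  co <- tiny_cohort()
  run <- co$runs[[1]]
  rois <- roi_set("flat", matrix(c(8, 8, 6), 1))
  run$data[8, 8, 6, ] <- 5
  expect_error(seed_fc_map(preprocess_run(run, smooth = FALSE), rois),
               class = "fcparcel_degenerate_error")
})
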