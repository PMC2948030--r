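# Detrending, band-pass filtering, Gaussian smoothing.

test_that("linear detrending removes ramps and constants exactly", {
  expect_equal(detrend_linear(c(1, 2, 3, 4)), rep(0, 4), tolerance = 1e-12)
  expect_equal(detrend_linear(c(5, 5, 5, 5)), rep(0, 4), tolerance = 1e-12)
  set.seed(1)
  x <- rnorm(50)
  r <- detrend_linear(x)
  expect_lt(abs(sum(r)), 1e-8)
  expect_lt(abs(sum(r * seq_along(r))), 1e-6)
  # oracle: identical to lm residuals
  expect_equal(r, unname(resid(lm(x ~ seq_along(x)))), tolerance = 1e-10)
  expect_error(detrend_linear(1), class = "fcparcel_size_error")
})

test_that("band-pass gain passes 0.05 Hz, kills DC and 0.2 Hz (FFT oracle)", {
  tt <- (0:199) * 2
  s_in <- sin(2 * pi * 0.05 * tt)
  y <- bandpass(s_in, 2, 0.01, 0.1)
  expect_gte(var(y) / var(s_in), 0.81)
  const <- rep(3, 200)
  expect_lt(max(abs(bandpass(const, 2, 0.01, 0.1))), 1e-6 * 3)
  s_out <- sin(2 * pi * 0.2 * tt)
  expect_lte(var(bandpass(s_out, 2, 0.01, 0.1)) / var(s_out), 0.01)
})

test_that("band-pass filtering is linear and validates its band", {
  set.seed(2)
  x <- rnorm(120); y <- rnorm(120)
  lhs <- bandpass(3 * x - 2 * y, 2, 0.01, 0.1)
  rhs <- 3 * bandpass(x, 2, 0.01, 0.1) - 2 * bandpass(y, 2, 0.01, 0.1)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_error(bandpass(x, 2, 0.1, 0.01), class = "fcparcel_config_error")
  expect_error(bandpass(x, 2, 0.01, 0.4), class = "fcparcel_config_error")
})

test_that("smoothing an impulse gives the discrete Gaussian kernel", {
  d <- c(15, 15, 15)
  v <- array(0, d); v[8, 8, 8] <- 1
  out <- smooth_gaussian(v, 8, c(4, 4, 4))
  expect_equal(sum(out), 1, tolerance = 1e-3)
  # kernel oracle along one axis: sigma = 8 / (2.3548 * 4) = 0.849 voxels
  sig <- 8 / (2 * sqrt(2 * log(2))) / 4
  expect_equal(sig, 0.849, tolerance = 1e-3)
  prof <- out[8 + (-3:3), 8, 8] / out[8, 8, 8]
  expect_equal(prof, dnorm(-3:3, sd = sig) / dnorm(0, sd = sig),
               tolerance = 1e-6)
})

test_that("smoothing preserves constants, sums, and fwhm 0 is the identity", {
  d <- c(10, 10, 8)
  mask <- array(TRUE, d)
  u <- array(7, d)
  su <- smooth_gaussian(u, 8, c(4, 4, 5), mask)
  expect_equal(su, u, tolerance = 1e-6) # mask renormalization keeps constants
  set.seed(3)
  v <- array(rnorm(prod(d)), d)
  expect_identical(smooth_gaussian(v, 0, c(4, 4, 5), mask), v)
  # interior-supported signal: total sum preserved to 0.1%
  w <- array(0, d); w[4:7, 4:7, 4:5] <- abs(rnorm(32)) + 1
  sw <- smooth_gaussian(w, 6, c(4, 4, 5), mask)
  expect_equal(sum(sw), sum(w), tolerance = 1e-3)
  expect_error(smooth_gaussian(v, -1, c(4, 4, 5)),
               class = "fcparcel_value_error")
})

test_that("spatial smoothing commutes with temporal filtering", {
  d <- c(8, 8, 6, 40)
  set.seed(4)
  arr <- array(rnorm(prod(d)), d)
  mask <- array(TRUE, d[1:3])
  a <- smooth_gaussian(arr, 6, c(4, 4, 5), mask)
  Y <- t(matrix(a, prod(d[1:3]), d[4]))
  a <- array(t(bandpass(detrend_linear(Y), 2, 0.01, 0.1)), d)
  Y2 <- t(matrix(arr, prod(d[1:3]), d[4]))
  b <- array(t(bandpass(detrend_linear(Y2), 2, 0.01, 0.1)), d)
  b <- smooth_gaussian(b, 6, c(4, 4, 5), mask)
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("preprocess_run keeps shape, finiteness, and rejects NaN input", {
  co <- tiny_cohort()
  run <- co$runs[[1]]
  pre <- preprocess_run(run)
  expect_identical(dim(pre$data), dim(run$data))
  expect_true(all(is.finite(pre$data)))
  bad <- run
  bad$data[1, 1, 1, 5] <- NaN
  expect_error(preprocess_run(bad), class = "fcparcel_nonfinite_error")
})
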