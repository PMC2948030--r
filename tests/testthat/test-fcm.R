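# PCA reduction, fuzzy c-means, Xie-Beni selection, hardening.

test_that("PCA keeps at least the requested variance and finds low rank", {
  set.seed(40)
  # rank-2 data: two factors
  f <- matrix(rnorm(2 * 60), 2, 60)
  L <- matrix(rnorm(40 * 2), 40, 2)
  X <- L %*% f
  red <- pca_reduce(X, 0.9)
  expect_lte(red$d, 2)
  expect_gte(sum(red$explained[seq_len(red$d)]), 0.9)
  # var_frac 1 reconstructs exactly (full basis)
  Xn <- X + matrix(rnorm(40 * 60, sd = 0.1), 40)
  red1 <- pca_reduce(Xn, 1)
  Xz <- t(scale(t(Xn)))
  Xc <- sweep(Xz, 2, colMeans(Xz))
  sv <- svd(Xc)
  recon <- red1$scores %*% t(sv$v[, seq_len(red1$d)])
  expect_equal(recon, Xc, tolerance = 1e-8, ignore_attr = TRUE)
  # random noise needs many components for 90%
  expect_gt(pca_reduce(matrix(rnorm(50 * 80), 50), 0.9)$d, 10)
})

test_that("constant voxel rows are dropped with a warning", {
  X <- rbind(matrix(rnorm(5 * 30), 5), rep(1, 30))
  expect_warning(red <- pca_reduce(X, 0.9), "constant")
  expect_identical(red$kept_rows, 1:5)
})

test_that("fcm with c = 1 returns full membership on the column means", {
  X <- matrix(rnorm(60), 20, 3)
  p <- fcm(X, 1)
  expect_true(all(p$memberships == 1))
  expect_equal(as.numeric(p$centroids), colMeans(X))
})

test_that("fcm hardening equals the exhaustive 2-means oracle on separated blobs", {
  tb <- two_blobs(n_per = 8, sep = 20)
  oracle <- brute_two_means(tb$X)
  p <- fcm(tb$X, 2, m = 2, seed = 41)
  expect_true(same_up_to_permutation(harden(p), oracle$labels, 2))
})

test_that("membership rows sum to 1 and the objective never increases", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(40 * 3), 40)
    p <- fcm(X, 3, m = 1.5, seed = s)
    expect_equal(rowSums(p$memberships), rep(1, 40), tolerance = 1e-6)
    expect_true(all(p$memberships >= 0 & p$memberships <= 1))
    expect_true(all(diff(p$objective) <= 1e-8 * p$objective[1]))
  }
})

test_that("a point equidistant from two symmetric clusters splits 50/50", {
  X <- rbind(cbind(rnorm(20, -10, 0.1), rnorm(20, 0, 0.1)),
             cbind(rnorm(20, 10, 0.1), rnorm(20, 0, 0.1)),
             c(0, 0))
  p <- fcm(X, 2, m = 2, seed = 42)
  expect_equal(as.numeric(p$memberships[41, ]), c(0.5, 0.5),
               tolerance = 0.05)
})

test_that("a point coinciding with a centroid gets membership 1", {
  X <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10))
  p <- fcm(X, 2, m = 2, seed = 43)
  expect_equal(max(p$memberships[1, ]), 1)
})

test_that("fcm validates its arguments", {
  X <- matrix(rnorm(20), 10)
  expect_error(fcm(X, 11), class = "fcparcel_value_error")
  expect_error(fcm(X, 2, m = 1), class = "fcparcel_value_error")
})

test_that("Xie-Beni selection finds the planted blob count", {
  fb <- four_blobs()
  sel <- select_n_clusters(fb$X, c_range = 2:8, m = 2, restarts = 5,
                           seed = 44)
  expect_identical(sel$c_star, 4L)
  tb <- two_blobs(n_per = 20)
  sel2 <- select_n_clusters(tb$X, c_range = 2:6, m = 2, restarts = 5,
                            seed = 45)
  expect_identical(sel2$c_star, 2L)
  expect_identical(nrow(sel$index_table), 7L)
})

test_that("hardened labelings are restart stable on separated blobs", {
  fb <- four_blobs()
  ref <- harden(fcm(fb$X, 4, m = 2, seed = 1))
  for (s in 2:10) {
    h <- harden(fcm(fb$X, 4, m = 2, seed = s))
    expect_true(same_up_to_permutation(h, ref, 4))
  }
})

test_that("hardening breaks ties toward the lowest cluster index", {
  p <- structure(list(memberships = rbind(c(0.9, 0.1), c(0.5, 0.5)),
                      centroids = matrix(0, 2, 2), fuzziness_m = 2,
                      objective = 0, n_iter = 1L),
                 class = "fuzzy_partition")
  expect_identical(harden(p), c(1L, 1L))
})
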