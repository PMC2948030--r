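## PCA reduction, fuzzy c-means, Xie-Beni cluster-count selection.

#' PCA reduction of voxel time courses
#'
#' Rows (voxels) are z-scored, then projected on the smallest number of
#' principal components whose cumulative explained variance reaches
#' `var_frac` (default 0.90). Constant rows are dropped with a warning.
#'
#' @param X Numeric matrix, voxels x time points.
#' @param var_frac Minimum cumulative explained-variance fraction.
#' @return List: `scores` (voxels x d), `explained` (per-component
#'   fractions), `d`, and `kept_rows` (indices of non-constant rows).
#' @export
pca_reduce <- function(X, var_frac = 0.90) {
  stop_if_not(var_frac > 0 && var_frac <= 1, "var_frac must be in (0, 1]",
              class = "fcparcel_value_error")
  stop_if_not(nrow(X) >= 2 && ncol(X) >= 2, "X must be at least 2 x 2",
              class = "fcparcel_value_error")
  sds <- apply(X, 1, stats::sd)
  keep <- which(sds > 0)
  if (length(keep) < nrow(X)) {
    warning(sprintf("dropping %d constant voxel row(s) before z-scoring",
                    nrow(X) - length(keep)))
    X <- X[keep, , drop = FALSE]
  }
  Xz <- (X - rowMeans(X)) / apply(X, 1, stats::sd)
  Xc <- sweep(Xz, 2, colMeans(Xz))
  sv <- svd(Xc)
  ev <- sv$d^2
  explained <- ev / sum(ev)
  d <- which(cumsum(explained) >= var_frac - 1e-12)[1]
  scores <- sv$u[, seq_len(d), drop = FALSE] %*%
    diag(sv$d[seq_len(d)], d, d)
  list(scores = scores, explained = explained, d = d, kept_rows = keep)
}

#' Fuzzy c-means clustering
#'
#' Standard alternating updates: memberships
#' `u_ik = 1 / sum_j (d_ik / d_jk)^(2/(m-1))` and centroids
#' `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`, iterated from seeded random
#' distinct rows until the maximum membership change drops below `tol`.
#' Voxels coinciding with a centroid get membership 1 there.
#'
#' @param X Numeric matrix, n observations x d features.
#' @param c Number of clusters (`1 <= c <= n`).
#' @param m Fuzziness exponent, `> 1` (default 1.3; see Details).
#' @param tol Convergence tolerance on memberships (default 1e-5).
#'
#' @details
#' The usable range of `m` depends strongly on the feature dimension. In
#' high-dimensional spaces (tens of PCA components of voxel time courses),
#' exponents of 2 and above drive all memberships toward `1/c` and the
#' centroids collapse onto the grand mean — a known degeneracy of fuzzy
#' c-means. The default `m = 1.3` keeps memberships graded (soft boundary
#' voxels retain split memberships) while remaining stable up to hundreds
#' of dimensions; low-dimensional toy data tolerate the textbook `m = 2`.
#' @param max_iter Iteration cap (default 300).
#' @param seed Integer seed for centroid initialization.
#' @return A `fuzzy_partition`: `memberships` (n x c), `centroids` (c x d),
#'   `fuzziness_m`, `objective` (per-iteration trajectory), `n_iter`.
#' @export
fcm <- function(X, c, m = 1.3, tol = 1e-5, max_iter = 300, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stop_if_not(c >= 1 && c <= n, "need 1 <= c <= n observations",
              class = "fcparcel_value_error")
  stop_if_not(m > 1, "fuzziness exponent m must be > 1",
              class = "fcparcel_value_error")
  if (c == 1) {
    ctr <- matrix(colMeans(X), 1)
    d2 <- rowSums((X - ctr[rep(1, n), , drop = FALSE])^2)
    return(structure(list(memberships = matrix(1, n, 1), centroids = ctr,
                          fuzziness_m = m, objective = sum(d2), n_iter = 0L),
                     class = "fuzzy_partition"))
  }
  C <- with_seed(seed, init_centroids(X, c))
  U <- NULL
  obj <- numeric(0)
  expo <- -1 / (m - 1)
  for (it in seq_len(max_iter)) {
    D2 <- pmax(dist2_to_centroids(X, C), 0)
    Unew <- memberships_from_dist(D2, expo)
    Um <- Unew^m
    obj <- c(obj, sum(Um * D2))
    denom <- colSums(Um)
    C <- sweep(t(Um) %*% X, 1, pmax(denom, 1e-300), "/")
    D2b <- pmax(dist2_to_centroids(X, C), 0)
    obj[length(obj)] <- sum(Um * D2b)
    if (!is.null(U) && max(abs(Unew - U)) < tol) {
      U <- Unew
      break
    }
    U <- Unew
  }
  structure(list(memberships = U, centroids = C, fuzziness_m = m,
                 objective = obj, n_iter = length(obj)),
            class = "fuzzy_partition")
}

init_centroids <- function(X, c, max_tries = 50) {
  n <- nrow(X)
  for (i in seq_len(max_tries)) {
    idx <- sample.int(n, c)
    C <- X[idx, , drop = FALSE]
    if (nrow(unique(C)) == c) return(C)
  }
  stop(errorCondition("could not draw distinct initial centroids",
                      class = c("fcparcel_degenerate_error", "error",
                                "condition")))
}

dist2_to_centroids <- function(X, C) {
  # n x c squared Euclidean distances
  outer(rowSums(X^2), rep(1, nrow(C))) + outer(rep(1, nrow(X)), rowSums(C^2)) -
    2 * X %*% t(C)
}

memberships_from_dist <- function(D2, expo) {
  n <- nrow(D2); c <- ncol(D2)
  U <- matrix(0, n, c)
  zero <- D2 < 1e-12
  anyzero <- rowSums(zero) > 0
  if (any(anyzero)) {
    zi <- which(anyzero)
    U[cbind(zi, max.col(-D2[zi, , drop = FALSE], ties.method = "first"))] <- 1
  }
  ok <- which(!anyzero)
  if (length(ok)) {
    P <- D2[ok, , drop = FALSE]^expo
    U[ok, ] <- P / rowSums(P)
  }
  U
}

#' Xie-Beni cluster-validity index
#'
#' Compactness over separation:
#' `sum_ik u_ik^m d_ik^2 / (n * min_(j != l) ||v_j - v_l||^2)`. Lower is
#' better.
#'
#' @param X Data matrix used for the partition.
#' @param partition A [fcm()] `fuzzy_partition` with `c >= 2`.
#' @return Scalar index.
#' @export
xie_beni <- function(X, partition) {
  C <- partition$centroids
  stop_if_not(nrow(C) >= 2, "Xie-Beni needs at least 2 clusters",
              class = "fcparcel_value_error")
  D2 <- pmax(dist2_to_centroids(as.matrix(X), C), 0)
  num <- sum(partition$memberships^partition$fuzziness_m * D2)
  sep <- min(stats::dist(C)^2)
  num / (nrow(X) * sep)
}

#' Unsupervised cluster-count selection
#'
#' Runs [fcm()] with multiple restarts for each candidate `c`, keeps the
#' restart with the lowest objective, scores it with the Xie-Beni index,
#' and returns the `c` minimizing the index.
#'
#' @param X Data matrix (n x d).
#' @param c_range Candidate cluster counts (default `2:8`).
#' @param m Fuzziness exponent (default 1.3).
#' @param restarts Restarts per candidate (default 10).
#' @param seed Integer seed.
#' @param ... Passed to [fcm()].
#' @return List: `c_star`, `index_table` (c, Xie-Beni index, objective),
#'   and `best_partitions` (best run per c).
#' @export
select_n_clusters <- function(X, c_range = 2:8, m = 1.3, restarts = 10,
                              seed = 1L, ...) {
  n <- nrow(as.matrix(X))
  stop_if_not(min(c_range) >= 2 && max(c_range) <= n - 1,
              "c_range must lie within [2, n - 1]",
              class = "fcparcel_value_error")
  best <- vector("list", length(c_range))
  xb <- numeric(length(c_range))
  for (i in seq_along(c_range)) {
    cc <- c_range[i]
    runs <- lapply(seq_len(restarts), function(r)
      fcm(X, cc, m = m, seed = child_seed(seed, cc * 1000 + r), ...))
    objs <- vapply(runs, function(p) p$objective[p$n_iter], numeric(1))
    best[[i]] <- runs[[which.min(objs)]]
    xb[i] <- xie_beni(X, best[[i]])
  }
  stop_if_not(any(is.finite(xb)), "all validity indices are non-finite",
              class = "fcparcel_degenerate_error")
  tab <- data.frame(c = c_range, xie_beni = xb,
                    objective = vapply(best, function(p)
                      p$objective[p$n_iter], numeric(1)))
  i_star <- which.min(xb)
  list(c_star = c_range[i_star], index_table = tab,
       best_partitions = stats::setNames(best, paste0("c", c_range)))
}

#' Harden a fuzzy partition
#'
#' Assigns each observation to its maximum-membership cluster; ties break to
#' the lowest cluster index.
#'
#' @param partition A `fuzzy_partition`.
#' @return Integer vector of cluster labels.
#' @export
harden <- function(partition) {
  max.col(partition$memberships, ties.method = "first")
}

#' Place per-voxel labels or memberships into a 3-D map
#'
#' @param values Vector (one per target voxel) of labels or memberships.
#' @param voxel_idx Linear voxel indices of the target-region rows.
#' @param grid_shape Length-3 voxel counts.
#' @return 3-D array, 0 outside the target region.
#' @export
labels_to_map <- function(values, voxel_idx, grid_shape) {
  out <- array(0, grid_shape)
  out[voxel_idx] <- values
  out
}
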