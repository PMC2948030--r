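## Connected components, Monte-Carlo cluster-extent calibration,
## cluster thresholding of t maps.

#' Label connected components of a 3-D binary array
#'
#' Face connectivity by default (6 neighbours); 18- and 26-connectivity are
#' available for comparability with other packages.
#'
#' @param mask 3-D logical array.
#' @param connectivity 6 (default), 18 or 26.
#' @return List: `labels` (integer 3-D array, 0 = background) and `sizes`
#'   (voxel count per component, decreasing).
#' @export
label_components <- function(mask, connectivity = 6) {
  stop_if_not(connectivity %in% c(6, 18, 26), "connectivity must be 6/18/26",
              class = "fcparcel_value_error")
  d <- dim(mask)
  mask <- array(as.logical(mask), d)
  idx <- which(mask)
  labels <- array(0L, d)
  if (length(idx) == 0) return(list(labels = labels, sizes = integer(0)))
  offs <- neighbour_offsets(connectivity)
  co <- arrayInd(idx, d)
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    hit <- mask[lin]
    if (any(hit)) {
      edges[[length(edges) + 1L]] <-
        cbind(pos[idx[ok]][hit], pos[lin[hit]])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relab <- integer(comp$no); relab[ord] <- seq_len(comp$no)
  labels[idx] <- relab[comp$membership]
  list(labels = labels, sizes = as.integer(sort(comp$csize, decreasing = TRUE)))
}

neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  # forward offsets only; undirected edges are symmetric
  g <- g[keep, , drop = FALSE]
  g[g[, 1] > 0 | (g[, 1] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 3] > 0))),
    , drop = FALSE]
}

#' Monte-Carlo calibration of the minimum cluster extent K
#'
#' Simulates `n_iter` independent Gaussian noise volumes on the mask,
#' smooths each to `fwhm_mm`, standardizes within the mask, thresholds
#' two-tailed at `voxel_p`, and records the maximum supra-threshold cluster
#' size (face connectivity). `K` is the smallest integer with
#' `P(max cluster >= K) <= alpha`.
#'
#' @param mask 3-D analysis mask.
#' @param fwhm_mm Smoothing FWHM applied to each noise volume (mm).
#' @param voxel_size_mm Length-3 voxel sizes (mm).
#' @param voxel_p Two-tailed voxelwise probability threshold.
#' @param alpha Cluster-level family-wise error target.
#' @param n_iter Number of simulated volumes (>= 100).
#' @param seed Integer seed.
#' @param connectivity Cluster connectivity (default 6).
#' @return Integer `K` with the simulated max-cluster distribution attached
#'   as attribute `max_sizes`.
#' @export
monte_carlo_cluster_threshold <- function(mask, fwhm_mm, voxel_size_mm,
                                          voxel_p = 0.01, alpha = 0.05,
                                          n_iter = 1000, seed = 1L,
                                          connectivity = 6) {
  stop_if_not(sum(mask) > 0, "mask is empty", class = "fcparcel_mask_error")
  stop_if_not(n_iter >= 100, "n_iter must be >= 100",
              class = "fcparcel_value_error")
  stop_if_not(voxel_p > 0 && voxel_p < 1 && alpha > 0 && alpha <= 1,
              "voxel_p and alpha must be probabilities",
              class = "fcparcel_value_error")
  d <- dim(mask)
  mask <- array(as.logical(mask), d)
  zthr <- stats::qnorm(1 - voxel_p / 2)
  max_sizes <- with_seed(seed, vapply(seq_len(n_iter), function(i) {
    v <- array(stats::rnorm(prod(d)), d)
    if (fwhm_mm > 0) v <- smooth_gaussian(v, fwhm_mm, voxel_size_mm, mask)
    vals <- v[mask]
    z <- (vals - mean(vals)) / stats::sd(vals)
    supra <- array(FALSE, d)
    supra[mask] <- abs(z) > zthr
    if (!any(supra)) return(0L)
    cc <- label_components(supra, connectivity)
    cc$sizes[1]
  }, integer(1)))
  # smallest K with empirical P(max >= K) <= alpha
  K <- 1L
  while (mean(max_sizes >= K) > alpha) K <- K + 1L
  structure(K, max_sizes = max_sizes)
}

#' Cluster-extent threshold a t map
#'
#' Applies the two-tailed voxelwise t threshold at `voxel_p` (using the
#' map's degrees of freedom), labels connected components of
#' supra-threshold voxels separately for positive and negative t, and keeps
#' components of at least `K` voxels. Positive clusters get positive label
#' ids, negative clusters negative ids.
#'
#' @param map A `stat_map`.
#' @param voxel_p Two-tailed voxelwise probability threshold.
#' @param K Minimum cluster extent in voxels (e.g. from
#'   [monte_carlo_cluster_threshold()]).
#' @param connectivity Cluster connectivity (default 6).
#' @return The `stat_map` with `labels`, `voxel_p` and `cluster_k` set.
#' @export
threshold_clusters <- function(map, voxel_p = 0.01, K = 1L,
                               connectivity = 6) {
  stopifnot(inherits(map, "stat_map"))
  stop_if_not(K >= 1, "K must be >= 1", class = "fcparcel_value_error")
  tthr <- stats::qt(1 - voxel_p / 2, df = map$dof)
  d <- dim(map$t_values)
  labels <- array(0L, d)
  nxt <- 0L
  for (sgn in c(1, -1)) {
    supra <- if (sgn > 0) map$t_values > tthr else map$t_values < -tthr
    if (!is.null(map$mask)) supra <- supra & as.logical(map$mask)
    if (!any(supra)) next
    cc <- label_components(supra, connectivity)
    keep <- which(cc$sizes >= K)
    for (ci in keep) {
      nxt <- nxt + 1L
      labels[cc$labels == ci] <- sgn * nxt
    }
  }
  map$labels <- labels
  map$voxel_p <- voxel_p
  map$cluster_k <- as.integer(K)
  map
}
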