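## Cross-subject cluster alignment, group probabilistic cluster maps,
## and network labeling of clusters.

#' Exact linear-assignment maximization
#'
#' Finds the permutation `p` maximizing `sum_i S[i, p[i]]` by dynamic
#' programming over column subsets (exact; O(c^2 2^c), fine for c <= 12).
#'
#' @param S Square score matrix (rows assigned to columns).
#' @return Integer permutation vector `p`.
#' @export
assign_max <- function(S) {
  S <- as.matrix(S)
  c <- nrow(S)
  stop_if_not(ncol(S) == c, "score matrix must be square",
              class = "fcparcel_value_error")
  nmask <- bitwShiftL(1L, c)
  best <- rep(-Inf, nmask); best[1] <- 0
  choice <- matrix(0L, c, nmask)
  counts <- vapply(0:(nmask - 1), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(c - 1))) > 0), integer(1))
  for (msk in 0:(nmask - 1)) {
    i <- counts[msk + 1] + 1L # next row to assign
    if (i > c || !is.finite(best[msk + 1])) next
    for (j in seq_len(c)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(msk, bit) > 0) next
      nm <- bitwOr(msk, bit)
      val <- best[msk + 1] + S[i, j]
      if (val > best[nm + 1]) {
        best[nm + 1] <- val
        choice[i, nm + 1] <- j
      }
    }
  }
  p <- integer(c)
  msk <- nmask - 1L
  for (i in rev(seq_len(c))) {
    j <- choice[i, msk + 1]
    p[i] <- j
    msk <- bitwAnd(msk, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  p
}

dice_binary <- function(a, b) {
  A <- sum(a); B <- sum(b); C <- sum(a & b)
  if (A + B == 0) return(1)
  2 * C / (A + B)
}

#' Align subjects' cluster labels across a cohort
#'
#' For each subject, finds the cluster-label permutation maximizing the
#' total Sorensen-Dice overlap of hardened labels against a reference
#' (exactly, by assignment optimization), then rebuilds a consensus
#' (per-voxel majority label) and re-matches every subject to it for a
#' fixed number of passes. The first subject seeds the initial reference.
#'
#' @param label_vectors List of integer label vectors (one per subject, same
#'   voxels in the same order, labels `1..c`).
#' @param c Number of clusters.
#' @param reference Optional reference label vector.
#' @param passes Consensus passes after the initial alignment (default 2).
#' @return List: `aligned` (list of relabeled vectors), `permutations`
#'   (list; `perm[old]` gives the new label), `consensus`.
#' @export
match_clusters <- function(label_vectors, c, reference = NULL, passes = 2) {
  nvox <- length(label_vectors[[1]])
  for (lv in label_vectors) {
    stop_if_not(length(lv) == nvox, "label vectors on different voxel sets",
                class = "fcparcel_grid_error")
    stop_if_not(all(lv >= 1 & lv <= c), "labels outside 1..c",
                class = "fcparcel_value_error")
  }
  ref <- if (is.null(reference)) label_vectors[[1]] else reference
  perms <- vector("list", length(label_vectors))
  aligned <- label_vectors
  for (pass in seq_len(passes + 1)) {
    for (s in seq_along(label_vectors)) {
      S <- matrix(0, c, c)
      for (a in seq_len(c)) for (b in seq_len(c))
        S[a, b] <- dice_binary(label_vectors[[s]] == a, ref == b)
      p <- assign_max(S)
      perms[[s]] <- p
      aligned[[s]] <- p[label_vectors[[s]]]
    }
    ref <- consensus_labels(aligned, c)
  }
  list(aligned = aligned, permutations = perms, consensus = ref)
}

consensus_labels <- function(aligned, c) {
  counts <- vapply(seq_len(c), function(k)
    Reduce(`+`, lapply(aligned, function(v) as.numeric(v == k))),
    numeric(length(aligned[[1]])))
  max.col(counts, ties.method = "first")
}

#' Group probabilistic cluster maps
#'
#' For each (aligned) cluster, the percentage of subjects assigning each
#' voxel to it. The raw values live in `[0, 100]`; `prob_map_display()`
#' applies the conventional 10% reporting floor.
#'
#' @param aligned List of aligned label vectors.
#' @param c Number of clusters.
#' @param voxel_idx Linear voxel indices of the parcellated region.
#' @param grid_shape Length-3 voxel counts.
#' @return List of `c` 3-D percent maps (class `cluster_prob_maps`).
#' @export
cluster_probability_maps <- function(aligned, c, voxel_idx, grid_shape) {
  maps <- lapply(seq_len(c), function(k) {
    freq <- Reduce(`+`, lapply(aligned, function(v) as.numeric(v == k)))
    labels_to_map(100 * freq / length(aligned), voxel_idx, grid_shape)
  })
  structure(maps, class = "cluster_prob_maps")
}

#' Apply the 10% display floor to a probability map
#'
#' Values in `(0, 10)` percent are suppressed to 0 on the reporting layer;
#' raw maps are left untouched.
#'
#' @param p Percent map (array).
#' @param floor_pct Reporting floor (default 10).
#' @return Floored copy of `p`.
#' @export
prob_map_display <- function(p, floor_pct = 10) {
  p[p < floor_pct] <- 0
  p
}

#' Label clusters by their dominant network
#'
#' Reconstructs each cluster's centroid time course as the
#' membership-weighted (`u^m`) mean of the voxel time courses, correlates it
#' with each candidate network course, and assigns labels injectively by
#' maximizing total correlation (exact assignment optimization). Clusters
#' whose top two correlations differ by less than `ambiguity` are flagged.
#'
#' @param partition A `fuzzy_partition`.
#' @param X Voxel x time matrix the partition was computed from (same rows).
#' @param network_courses Time x K matrix of candidate network courses
#'   (columns named).
#' @param ambiguity Flagging margin on the correlation gap (default 0.05).
#' @return Data frame: cluster, network label, correlation, ambiguous flag.
#' @export
label_clusters_by_network <- function(partition, X, network_courses,
                                      ambiguity = 0.05) {
  Um <- partition$memberships^partition$fuzziness_m
  cent_ts <- t(Um) %*% as.matrix(X) / pmax(colSums(Um), 1e-300) # c x time
  R <- stats::cor(t(cent_ts), network_courses) # c x K
  c <- nrow(R); K <- ncol(R)
  stop_if_not(c <= K, "more clusters than candidate networks",
              class = "fcparcel_value_error")
  Rpad <- cbind(R, matrix(-Inf, c, 0))
  if (c < K) {
    p_full <- assign_max(rbind(R, matrix(0, K - c, K)))
    p <- p_full[seq_len(c)]
  } else {
    p <- assign_max(Rpad)
  }
  gap <- apply(R, 1, function(r) {
    s <- sort(r, decreasing = TRUE)
    if (length(s) > 1) s[1] - s[2] else Inf
  })
  data.frame(cluster = seq_len(c),
             network = colnames(network_courses)[p],
             correlation = R[cbind(seq_len(c), p)],
             ambiguous = gap < ambiguity,
             stringsAsFactors = FALSE)
}
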