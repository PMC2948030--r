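## Design-matrix assembly, prewhitened GLM fitting, seed FC maps.

#' Build nuisance regressors from a BOLD run
#'
#' Extracts the global (whole-brain), white-matter and cerebrospinal-fluid
#' mean time courses and expands each into three covariates — the course,
#' its first temporal derivative and its square — yielding the conventional
#' nine tissue/global nuisance covariates, plus the six motion parameters.
#' `mode = "plain"` keeps only the three raw courses. All columns are
#' mean-centered; all-zero motion columns are dropped with a warning.
#'
#' @param run A `bold_run`.
#' @param mode `"expanded"` (3 sources x 3 terms = 9 covariates, default) or
#'   `"plain"` (3 covariates).
#' @return Matrix of nuisance columns with a `roles` attribute.
#' @export
build_nuisance <- function(run, mode = c("expanded", "plain")) {
  mode <- match.arg(mode)
  d <- dim(run$data)
  Y <- matrix(run$data, prod(d[1:3]), d[4])
  src <- list(global = run$brain_mask, wm = run$wm_mask, csf = run$csf_mask)
  for (nm in c("wm", "csf"))
    stop_if_not(sum(src[[nm]]) > 0, sprintf("%s mask is empty", nm),
                class = "fcparcel_mask_error")
  courses <- vapply(src, function(m) colMeans(Y[as.logical(m), , drop = FALSE]),
                    numeric(d[4]))
  expand <- function(x, nm) {
    x <- x - mean(x)
    if (mode == "plain") {
      out <- matrix(x, ncol = 1)
      colnames(out) <- nm
      return(out)
    }
    dx <- c(0, diff(x))
    sq <- x^2
    out <- cbind(x, dx - mean(dx), sq - mean(sq))
    colnames(out) <- paste0(nm, c("", "_deriv", "_sq"))
    out
  }
  tissue <- do.call(cbind, lapply(names(src), function(nm)
    expand(courses[, nm], nm)))
  motion <- run$motion
  keep <- apply(motion, 2, function(m) stats::sd(m) > 0)
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance motion column(s)",
                    sum(!keep)))
    motion <- motion[, keep, drop = FALSE]
  }
  if (ncol(motion) > 0) motion <- scale(motion, scale = FALSE)
  X <- cbind(tissue, motion)
  attr(X, "roles") <- c(rep("nuisance_tissue", ncol(tissue)),
                        rep("motion", ncol(motion)))
  X
}

#' Orthogonalize seed time courses in ROI order
#'
#' Z-normalizes each seed course, then applies sequential Gram-Schmidt in
#' the given order so that each seed regressor carries only the variance not
#' explained by earlier seeds; every output is re-z-normalized. The first
#' seed is unchanged apart from z-normalization. Note the result depends on
#' the seed order.
#'
#' @param seed_ts List of numeric vectors (equal lengths), optionally named.
#' @return List of orthogonal z-normalized series.
#' @export
orthogonalize_seeds <- function(seed_ts) {
  stop_if_not(length(seed_ts) >= 1, "need at least one seed series",
              class = "fcparcel_value_error")
  n <- length(seed_ts[[1]])
  stop_if_not(all(vapply(seed_ts, length, integer(1)) == n),
              "seed series have unequal lengths",
              class = "fcparcel_value_error")
  nm <- names(seed_ts)
  if (is.null(nm)) nm <- paste0("seed", seq_along(seed_ts))
  out <- vector("list", length(seed_ts))
  for (i in seq_along(seed_ts)) {
    v <- znorm(seed_ts[[i]])
    if (i > 1) {
      for (pass in 1:2) { # double Gram-Schmidt for numerical orthogonality
        for (j in seq_len(i - 1)) {
          v <- v - sum(v * out[[j]]) / sum(out[[j]]^2) * out[[j]]
        }
      }
      stop_if_not(stats::sd(v) > 1e-8 * sqrt(n),
                  sprintf("seed '%s' is collinear with earlier seeds", nm[i]),
                  class = "fcparcel_collinearity_error")
    }
    out[[i]] <- znorm(v)
  }
  names(out) <- nm
  out
}

#' Estimate AR(1) autocorrelation and quasi-difference a GLM
#'
#' Fits ordinary least squares, estimates the lag-1 autocorrelation `rho` of
#' the residuals, and applies the Cochrane-Orcutt transform
#' `y'_t = y_t - rho * y_(t-1)` (dropping the first observation) to the
#' response and every design column. Estimates with `|rho| >= 0.95` are
#' clipped with a warning. `rho = 0` returns the inputs unchanged.
#'
#' @param y Response vector.
#' @param X Design matrix (including intercept).
#' @return List with `y`, `X`, and the estimated `rho`.
#' @export
prewhiten <- function(y, X) {
  n <- length(y)
  stop_if_not(n > ncol(X) + 2, "too few time points for prewhitening",
              class = "fcparcel_size_error")
  r <- stats::lm.fit(X, y)$residuals
  # numerically exact fits carry no autocorrelation information
  rho <- if (sum(r^2) <= 1e-20 * sum(y^2)) 0 else ar1_coef(r)
  if (abs(rho) >= 0.95) {
    warning(sprintf("AR(1) estimate %.3f clipped to %s0.95", rho,
                    if (rho > 0) "" else "-"))
    rho <- sign(rho) * 0.95
  }
  if (rho == 0) return(list(y = y, X = X, rho = 0))
  idx <- 2:n
  list(y = y[idx] - rho * y[idx - 1],
       X = X[idx, , drop = FALSE] - rho * X[idx - 1, , drop = FALSE],
       rho = rho)
}

ar1_coef <- function(r) {
  n <- length(r)
  denom <- sum(r^2)
  if (denom <= 0) return(0)
  sum(r[-1] * r[-n]) / denom
}

#' Ordinary least-squares GLM with t statistics
#'
#' @param y Response vector.
#' @param X Full-column-rank design matrix.
#' @param t_cap Cap on `|t|` for numerically exact fits (default 1e6); capped
#'   values are flagged in the `exact_fit` field.
#' @return List: `beta`, `se`, `t`, `dof`, `sigma2`, `exact_fit`.
#' @export
fit_glm <- function(y, X, t_cap = 1e6) {
  n <- length(y); p <- ncol(X)
  stop_if_not(n > p, "more parameters than observations",
              class = "fcparcel_rank_error")
  qx <- qr(X)
  if (qx$rank < p) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop(errorCondition(
      sprintf("design matrix is rank deficient; dependent columns: %s",
              paste(dep, collapse = ", ")),
      class = c("fcparcel_rank_error", "error", "condition")))
  }
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  dof <- n - p
  sigma2 <- sum(res^2) / dof
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
  exact <- sigma2 < 1e-20 * mean(y^2 + 1e-300)
  tt <- ifelse(se > 0, beta / se, sign(beta) * t_cap)
  tt <- pmin(pmax(tt, -t_cap), t_cap)
  list(beta = as.numeric(beta), se = se, t = as.numeric(tt), dof = dof,
       sigma2 = sigma2, exact_fit = exact)
}

#' Voxelwise seed functional-connectivity maps
#'
#' Fits one joint prewhitened GLM per voxel — intercept, all orthogonalized
#' seed regressors, nine tissue/global nuisance covariates and six motion
#' parameters — over every brain-mask voxel, and returns one t/beta map per
#' seed. AR(1) prewhitening is per voxel; estimated coefficients are rounded
#' to a 0.01 grid so voxels sharing a coefficient are refit in one batch.
#'
#' @param run A preprocessed `bold_run`.
#' @param rois A validated [roi_set()].
#' @param nuisance_mode Passed to [build_nuisance()].
#' @param orthogonalize Orthogonalize seeds sequentially (default `TRUE`);
#'   when `FALSE` each seed is fit in its own model (robustness variant).
#' @param prewhiten_data Apply AR(1) prewhitening (default `TRUE`).
#' @return A named list (one entry per seed) of `stat_map` objects carrying
#'   `t_values`, `beta`, `dof` and the analysis mask.
#' @export
seed_fc_map <- function(run, rois, nuisance_mode = "expanded",
                        orthogonalize = TRUE, prewhiten_data = TRUE) {
  d <- dim(run$data)
  seeds_raw <- lapply(seq_len(nrow(rois)), function(i)
    extract_roi_timecourse(run, rois[i, ]))
  names(seeds_raw) <- rois$label
  for (s in seeds_raw)
    stop_if_not(stats::sd(s) > 1e-8,
                "a seed regressor is constant/all zeros",
                class = "fcparcel_degenerate_error")
  nuis <- build_nuisance(run, mode = nuisance_mode)
  # Residualize seed courses on the nuisance set (plus intercept) before any
  # seed-to-seed orthogonalization: shared global/tissue/motion variance is
  # not "unique seed variance", and leaving it in the first seed would leak
  # sign-flipped copies of it into every later orthogonalized regressor. By
  # Frisch-Waugh this leaves single-seed models' estimates unchanged.
  Xn <- cbind(1, nuis)
  seeds_raw <- lapply(seeds_raw, function(s)
    as.numeric(stats::lm.fit(Xn, s)$residuals))
  mask <- as.logical(run$brain_mask)
  Y <- matrix(run$data, prod(d[1:3]), d[4])[mask, , drop = FALSE]
  Y <- t(Y) # time x voxels

  fit_set <- function(seed_list) {
    S <- do.call(cbind, seed_list)
    X <- cbind(intercept = 1, S, nuis)
    colnames(X) <- c("intercept", names(seed_list), colnames(nuis))
    qx <- qr(X)
    stop_if_not(qx$rank == ncol(X), "design matrix is rank deficient",
                class = "fcparcel_rank_error")
    glm_voxelwise(Y, X, seed_cols = 1 + seq_along(seed_list),
                  prewhiten_data = prewhiten_data)
  }

  if (orthogonalize) {
    seeds <- orthogonalize_seeds(seeds_raw)
    res <- fit_set(seeds)
    per_seed <- lapply(seq_along(seeds), function(k)
      list(t = res$t[k, ], beta = res$beta[k, ], dof = res$dof))
  } else {
    seeds <- lapply(seeds_raw, znorm)
    per_seed <- lapply(seq_along(seeds), function(k) {
      r1 <- fit_set(seeds[k])
      list(t = r1$t[1, ], beta = r1$beta[1, ], dof = r1$dof)
    })
  }
  names(per_seed) <- rois$label
  lapply(per_seed, function(ps) {
    tmap <- array(0, d[1:3]); tmap[mask] <- ps$t
    bmap <- array(0, d[1:3]); bmap[mask] <- ps$beta
    stat_map(tmap, dof = ps$dof, mask = run$brain_mask, beta = bmap)
  })
}

# Batched voxelwise prewhitened OLS: shared design X, many responses.
# Returns seed-row matrices of t and beta (seed_cols x n_voxels).
glm_voxelwise <- function(Y, X, seed_cols, prewhiten_data = TRUE,
                          rho_bin = 0.01) {
  nt <- nrow(Y); p <- ncol(X); nv <- ncol(Y)
  ols <- function(Xd, Yd) {
    qx <- qr(Xd)
    B <- qr.coef(qx, Yd)
    R <- Yd - Xd %*% B
    dof <- nrow(Yd) - p
    sig2 <- colSums(R^2) / dof
    cjj <- diag(chol2inv(qr.R(qx)))
    SE <- sqrt(pmax(outer(cjj, sig2), 1e-300))
    # numerically exact fits (e.g. a single-voxel seed regressing on
    # itself) are capped rather than reported as astronomical t values
    Tm <- pmin(pmax(B / SE, -1e6), 1e6)
    list(B = B, T = Tm, resid = R, dof = dof)
  }
  first <- ols(X, Y)
  if (!prewhiten_data) {
    return(list(t = first$T[seed_cols, , drop = FALSE],
                beta = first$B[seed_cols, , drop = FALSE], dof = first$dof))
  }
  rho <- apply(first$resid, 2, ar1_coef)
  rho <- pmin(pmax(rho, -0.95), 0.95)
  rho_b <- round(rho / rho_bin) * rho_bin
  tmat <- matrix(NA_real_, length(seed_cols), nv)
  bmat <- matrix(NA_real_, length(seed_cols), nv)
  for (r in unique(rho_b)) {
    sel <- which(rho_b == r)
    if (r == 0) {
      tmat[, sel] <- first$T[seed_cols, sel]
      bmat[, sel] <- first$B[seed_cols, sel]
      next
    }
    idx <- 2:nt
    Xw <- X[idx, , drop = FALSE] - r * X[idx - 1, , drop = FALSE]
    Yw <- Y[idx, sel, drop = FALSE] - r * Y[idx - 1, sel, drop = FALSE]
    fw <- ols(Xw, Yw)
    tmat[, sel] <- fw$T[seed_cols, , drop = FALSE]
    bmat[, sel] <- fw$B[seed_cols, , drop = FALSE]
  }
  list(t = tmat, beta = bmat, dof = nt - 1 - p)
}

#' Construct a statistical map object
#'
#' @param t_values 3-D array of t statistics.
#' @param dof Residual degrees of freedom.
#' @param mask Analysis mask.
#' @param beta Optional 3-D array of effect sizes.
#' @param voxel_p,cluster_k,corrected_alpha Thresholding metadata (set by
#'   [threshold_clusters()]).
#' @param labels Optional 3-D signed cluster-index map.
#' @return A `stat_map` object.
#' @export
stat_map <- function(t_values, dof, mask = NULL, beta = NULL, voxel_p = NA,
                     cluster_k = NA, corrected_alpha = NA, labels = NULL) {
  stop_if_not(dof >= 1, "dof must be >= 1", class = "fcparcel_value_error")
  structure(list(t_values = t_values, dof = as.integer(dof), mask = mask,
                 beta = beta, voxel_p = voxel_p, cluster_k = cluster_k,
                 corrected_alpha = corrected_alpha, labels = labels),
            class = "stat_map")
}
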