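## Group-level random-effects analysis and probability maps.

#' Random-effects group map controlling for age and sex
#'
#' Fits, at each voxel, an ordinary least-squares model of the per-subject
#' effect sizes on an intercept, mean-centered age and a sex indicator, and
#' reports the intercept's t statistic with `n - 3` degrees of freedom.
#' Voxels with zero between-subject residual variance are flagged as
#' undefined (`NaN`).
#'
#' @param subject_maps List of per-subject 3-D effect-size (beta) maps.
#' @param age Numeric vector of ages (years).
#' @param sex Character/factor vector (two levels).
#' @param mask Optional 3-D analysis mask.
#' @return A `stat_map` of group t values (dof = n - 3) with the undefined
#'   voxel flags in attribute `undefined`.
#' @export
group_random_effects <- function(subject_maps, age, sex, mask = NULL) {
  n <- length(subject_maps)
  stop_if_not(n >= 3, "need at least 3 subjects", class = "fcparcel_value_error")
  stop_if_not(length(age) == n && length(sex) == n && !anyNA(age) && !anyNA(sex),
              "age/sex covariates must be complete",
              class = "fcparcel_value_error")
  d <- dim(subject_maps[[1]])
  for (m in subject_maps)
    stop_if_not(identical(dim(m), d), "subject maps on different grids",
                class = "fcparcel_grid_error")
  if (is.null(mask)) mask <- array(TRUE, d)
  mask <- array(as.logical(mask), d)
  B <- t(vapply(subject_maps, function(m) m[mask], numeric(sum(mask))))
  X <- cbind(intercept = 1, age_c = age - mean(age),
             sex = as.numeric(factor(sex)) - mean(as.numeric(factor(sex))))
  p <- ncol(X)
  qx <- qr(X)
  stop_if_not(qx$rank == p, "covariate design is rank deficient",
              class = "fcparcel_rank_error")
  Bh <- qr.coef(qx, B)
  R <- B - X %*% Bh
  dof <- n - p
  sig2 <- colSums(R^2) / dof
  c11 <- chol2inv(qr.R(qx))[1, 1]
  se <- sqrt(sig2 * c11)
  tvals <- ifelse(se > 0, Bh[1, ] / se, NaN)
  tmap <- array(0, d)
  tmap[mask] <- tvals
  undef <- array(FALSE, d)
  undef[mask] <- !is.finite(tvals)
  tmap[undef] <- 0
  out <- stat_map(tmap, dof = dof, mask = mask)
  attr(out, "undefined") <- undef
  out
}

#' Voxelwise probability map across subjects
#'
#' Percentage of subjects in which each voxel is positive (supra-threshold
#' or assigned), i.e. `100 * count / n`.
#'
#' @param binary_maps List of 3-D binary (0/1 or logical) maps on one grid.
#' @return 3-D numeric array of percentages in `[0, 100]`.
#' @export
probability_map <- function(binary_maps) {
  stop_if_not(length(binary_maps) >= 1, "need at least one map",
              class = "fcparcel_value_error")
  d <- dim(binary_maps[[1]])
  for (m in binary_maps)
    stop_if_not(identical(dim(m), d), "maps on different grids",
                class = "fcparcel_grid_error")
  acc <- array(0, d)
  for (m in binary_maps) acc <- acc + (as.numeric(m) > 0)
  100 * acc / length(binary_maps)
}
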