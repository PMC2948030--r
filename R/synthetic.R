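## Synthetic multi-subject BOLD cohorts with planted network structure.
##
## The generator emulates a desk-scale resting-state acquisition: four
## low-frequency networks (an anticorrelated task-positive/task-negative
## pair, a sensorimotor-like and a visual-like network), a target region
## whose voxels mix adjacent network signals, tissue/global/motion nuisance
## components, and AR(1) voxel noise.

#' Simulation configuration
#'
#' Defaults mirror a typical single-session resting-state protocol:
#' 16 subjects, 200 volumes at TR 2 s, network signals confined to
#' 0.01-0.1 Hz. `snr` is the ratio of network-signal to noise standard
#' deviation at a voxel with network weight 1.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param n_volumes Volumes per run (default 200; must be >= 32).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param band_hz Frequency band of the planted network signals (Hz).
#' @param snr Signal-to-noise ratio at a weight-1 voxel (default 1).
#' @param noise_ar1 Lag-1 autocorrelation of voxel noise in `[0, 1)`.
#' @param nuisance_amplitudes Named list of amplitudes for `global`, `wm`,
#'   `csf` and `motion` nuisance components (in noise-sd units).
#' @param seed Integer seed controlling every random draw.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 16, n_volumes = 200, tr_seconds = 2,
                       band_hz = c(0.01, 0.1), snr = 1, noise_ar1 = 0.3,
                       nuisance_amplitudes = list(global = 0.5, wm = 0.5,
                                                  csf = 0.5, motion = 0.3),
                       seed = 42) {
  nyq <- 1 / (2 * tr_seconds)
  stop_if_not(n_volumes >= 32, "n_volumes must be at least 32",
              class = "fcparcel_config_error")
  stop_if_not(band_hz[1] > 0 && band_hz[1] < band_hz[2] && band_hz[2] < nyq,
              sprintf("band [%g, %g] Hz invalid for TR %g s",
                      band_hz[1], band_hz[2], tr_seconds),
              class = "fcparcel_config_error")
  stop_if_not(snr > 0, "snr must be positive", class = "fcparcel_config_error")
  stop_if_not(noise_ar1 >= 0 && noise_ar1 < 1, "noise_ar1 must be in [0, 1)",
              class = "fcparcel_config_error")
  for (nm in c("global", "wm", "csf", "motion"))
    stop_if_not(!is.null(nuisance_amplitudes[[nm]]),
                sprintf("nuisance_amplitudes$%s missing", nm),
                class = "fcparcel_config_error")
  structure(list(n_subjects = n_subjects, n_volumes = n_volumes,
                 tr_seconds = tr_seconds, band_hz = band_hz, snr = snr,
                 noise_ar1 = noise_ar1,
                 nuisance_amplitudes = nuisance_amplitudes,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default network atlas: four planted networks and a target band
#'
#' Lays out four spatially contiguous network supports inside an ellipsoidal
#' brain mask. Two networks (TPN, TNN) form the anticorrelated pair and have
#' disjoint supports; all four intersect a target band of voxels (the
#' "posteromedial-analog" region) along which network dominance shifts
#' smoothly, so target voxels mix adjacent network signals. The layout is a
#' deterministic function of the grid; `seed` is carried for bookkeeping
#' only.
#'
#' @param grid_shape Length-3 voxel counts (default `c(24, 24, 18)`).
#' @param voxel_size_mm Length-3 voxel size in mm (default `c(4, 4, 5)`).
#' @param seed Integer, recorded in the atlas.
#' @return A `network_atlas`: weight maps, labels
#'   (`TPN`, `TNN`, `MOT`, `VIS`), the anticorrelated pair, target mask and
#'   brain/GM/WM/CSF masks.
#' @export
make_default_atlas <- function(grid_shape = c(24, 24, 18),
                               voxel_size_mm = c(4, 4, 5), seed = 1L) {
  stop_if_not(all(grid_shape >= 8),
              "grid too small: need at least 8 voxels per dimension",
              class = "fcparcel_sizing_error")
  d <- as.integer(grid_shape)
  co <- grid_coords(d)
  ctr <- (d + 1) / 2

  ellipsoid <- function(center, semi) {
    v <- ((co[, 1] - center[1]) / semi[1])^2 +
      ((co[, 2] - center[2]) / semi[2])^2 +
      ((co[, 3] - center[3]) / semi[3])^2
    array(v <= 1, d)
  }
  brain <- ellipsoid(ctr, 0.48 * d)
  wm <- ellipsoid(c(0.5, 0.25, 0.5) * d, 0.14 * d) & brain
  csf <- ellipsoid(c(0.5, 0.75, 0.5) * d, 0.10 * d) & brain
  gm <- brain & !wm & !csf

  # Four network centres along the target band (x axis, mid y/z), spatial
  # order TPN, MOT, VIS, TNN so the anticorrelated pair is never adjacent;
  # each network also owns a distal blob elsewhere in the brain.
  y0 <- round(0.5 * d[2]); z0 <- round(0.5 * d[3])
  band_x <- seq(max(2, round(0.10 * d[1])), min(d[1] - 1, round(0.90 * d[1])))
  xs <- round(c(0.14, 0.38, 0.62, 0.86) * d[1])
  band_centers <- cbind(xs, y0, z0)[c(1, 4, 2, 3), , drop = FALSE] # TPN TNN MOT VIS
  distal <- rbind(c(0.25, 0.22, 0.40), c(0.75, 0.80, 0.60),
                  c(0.25, 0.78, 0.65), c(0.75, 0.25, 0.40))
  distal <- sweep(distal, 2, d, "*")
  r <- max(1.8, 0.09 * min(d))

  blob <- function(center, radius) {
    d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
      (co[, 3] - center[3])^2
    w <- exp(-d2 / (2 * radius^2))
    w[w < 0.05] <- 0
    array(w, d)
  }
  labels <- c("TPN", "TNN", "MOT", "VIS")
  weights <- lapply(seq_len(4), function(k) {
    w <- pmax(blob(band_centers[k, ], r), blob(distal[k, ], r))
    w[!gm] <- 0
    w
  })
  names(weights) <- labels
  # enforce disjoint supports for the anticorrelated pair
  both <- weights$TPN > 0 & weights$TNN > 0
  if (any(both)) {
    tpn_wins <- both & (weights$TPN >= weights$TNN)
    weights$TNN[tpn_wins] <- 0
    weights$TPN[both & !tpn_wins] <- 0
  }
  target <- array(FALSE, d)
  target[band_x, (y0 - 1):(y0 + 1), (z0 - 1):(z0 + 1)] <- TRUE
  target <- target & gm

  for (k in seq_len(4))
    stop_if_not(any(weights[[k]] > 0.5),
                sprintf("network %s has no strong voxel; grid too small",
                        labels[k]),
                class = "fcparcel_sizing_error")
  n_hit <- sum(vapply(weights, function(w) any(w[target] > 0), logical(1)))
  stop_if_not(n_hit >= 2, "target band intersects fewer than 2 networks",
              class = "fcparcel_sizing_error")
  structure(list(grid_shape = d, voxel_size_mm = voxel_size_mm,
                 weights = weights, labels = labels,
                 anticorrelated_pair = c(1L, 2L), target_mask = target,
                 brain_mask = brain, gm_mask = gm, wm_mask = wm,
                 csf_mask = csf, seed = as.integer(seed)),
            class = "network_atlas")
}

# Band-limited unit-variance series; two filter passes keep >=90% of the
# periodogram power strictly inside the band.
band_limited_noise <- function(n, tr, band, ncol = 1) {
  x <- matrix(stats::rnorm(n * ncol), n, ncol)
  x <- bandpass(bandpass(x, tr, band[1], band[2]), tr, band[1], band[2])
  x <- sweep(x, 2, colMeans(x))
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

#' Simulate the ground-truth network time courses
#'
#' Builds one unit-variance band-limited course per network from filtered
#' white noise, orthonormalized so that all pairwise correlations are zero
#' except the designated anticorrelated pair, which is constructed with
#' correlation -0.7 (negated course plus orthogonal band-limited residual).
#'
#' @param cfg A [sim_config()].
#' @param atlas A [make_default_atlas()] atlas.
#' @return A `ground_truth` with `network_timecourses`
#'   (time x networks), the target anticorrelation, and per-voxel expected
#'   correlation signs per network.
#' @export
simulate_network_timecourses <- function(cfg, atlas) {
  stopifnot(inherits(cfg, "sim_config"), inherits(atlas, "network_atlas"))
  K <- length(atlas$labels)
  courses <- with_seed(child_seed(cfg$seed, 0), {
    B <- band_limited_noise(cfg$n_volumes, cfg$tr_seconds, cfg$band_hz,
                            ncol = K)
    Q <- qr.Q(qr(B))
    Q <- sweep(Q, 2, colMeans(Q))
    Q <- sweep(Q, 2, apply(Q, 2, stats::sd), "/")
    a <- 0.7
    out <- Q
    i <- atlas$anticorrelated_pair[1]; j <- atlas$anticorrelated_pair[2]
    out[, j] <- -a * Q[, i] + sqrt(1 - a^2) * Q[, j]
    out[, j] <- out[, j] / stats::sd(out[, j])
    colnames(out) <- atlas$labels
    out
  })
  sign_maps <- lapply(seq_len(K), function(k) {
    s <- array(0L, atlas$grid_shape)
    s[atlas$weights[[k]] > 0] <- 1L
    partner <- if (k == atlas$anticorrelated_pair[1]) atlas$anticorrelated_pair[2]
      else if (k == atlas$anticorrelated_pair[2]) atlas$anticorrelated_pair[1]
      else NA_integer_
    if (!is.na(partner)) s[atlas$weights[[partner]] > 0] <- -1L
    s
  })
  names(sign_maps) <- atlas$labels
  structure(list(network_timecourses = courses,
                 anticorrelation = -0.7,
                 sign_maps = sign_maps,
                 subject_seeds = integer(0)),
            class = "ground_truth")
}

#' Simulate one subject's BOLD run
#'
#' Forward model per voxel: baseline + drift +
#' `snr * sum_k weight_k * course_k` + global/tissue nuisance courses +
#' motion-coupled leakage + AR(1) noise of unit marginal standard deviation.
#'
#' @param cfg A [sim_config()].
#' @param atlas A `network_atlas`.
#' @param truth Output of [simulate_network_timecourses()].
#' @param subject_index 1-based subject index (`<= cfg$n_subjects`).
#' @return A `bold_run`: 4-D data, masks, TR, a 200 x 6 motion table
#'   (mm / degrees), subject id and age/sex covariates.
#' @export
simulate_subject <- function(cfg, atlas, truth, subject_index) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "ground_truth"))
  stop_if_not(subject_index >= 1 && subject_index <= cfg$n_subjects,
              "subject_index out of range", class = "fcparcel_value_error")
  d <- atlas$grid_shape
  nt <- cfg$n_volumes
  nv <- prod(d)
  sseed <- child_seed(cfg$seed, subject_index)
  run <- with_seed(sseed, {
    rho <- cfg$noise_ar1
    innov <- matrix(stats::rnorm(nt * nv, sd = sqrt(1 - rho^2)), nt, nv)
    noise <- if (rho > 0) {
      apply(innov, 2, function(w) stats::filter(w, rho, method = "recursive"))
    } else innov
    W <- vapply(atlas$weights, as.numeric, numeric(nv)) # nv x K
    Y <- cfg$snr * (truth$network_timecourses %*% t(W)) + noise

    amp <- cfg$nuisance_amplitudes
    haz <- band_limited_noise(nt, cfg$tr_seconds, cfg$band_hz, ncol = 3)
    bm <- as.numeric(atlas$brain_mask); wmv <- as.numeric(atlas$wm_mask)
    csfv <- as.numeric(atlas$csf_mask)
    Y <- Y + amp$global * haz[, 1] %o% bm
    Y <- Y + amp$wm * haz[, 2] %o% wmv
    Y <- Y + amp$csf * haz[, 3] %o% csfv

    # smooth random-walk motion, kept within 1 mm / 1 degree
    motion <- vapply(seq_len(6), function(j) {
      p <- cumsum(stats::rnorm(nt))
      p <- stats::filter(p, rep(1 / 5, 5), sides = 2)
      p[is.na(p)] <- 0
      0.8 * p / max(abs(p), 1e-12)
    }, numeric(nt))
    colnames(motion) <- c("tx_mm", "ty_mm", "tz_mm",
                          "rx_deg", "ry_deg", "rz_deg")
    Mz <- scale(motion)
    load <- matrix(stats::rnorm(6 * nv, sd = amp$motion / sqrt(6)), 6, nv)
    load[, bm == 0] <- 0
    Y <- Y + Mz %*% load

    baseline <- 100 * bm
    drift <- stats::rnorm(nv, sd = 0.5) * bm
    Y <- Y + rep(1, nt) %o% baseline +
      (seq_len(nt) / nt) %o% drift
    list(data = array(t(Y), c(d, nt)), motion = motion)
  })
  structure(list(data = run$data, tr_seconds = cfg$tr_seconds,
                 voxel_size_mm = atlas$voxel_size_mm,
                 brain_mask = atlas$brain_mask, gm_mask = atlas$gm_mask,
                 wm_mask = atlas$wm_mask, csf_mask = atlas$csf_mask,
                 motion = run$motion,
                 subject_id = sprintf("sub-%02d", subject_index),
                 age = NA_real_, sex = NA_character_, seed = sseed),
            class = "bold_run")
}

#' Simulate a whole cohort
#'
#' Applies [simulate_subject()] for each subject against a shared atlas and
#' shared ground-truth network courses, attaches age/sex covariates
#' (ages drawn uniformly in 23-75, sexes balanced), and optionally writes
#' NIfTI volumes, motion tables and a ground-truth manifest to
#' `output_dir`.
#'
#' @param cfg A [sim_config()].
#' @param atlas Optional atlas; the default atlas is built when `NULL`.
#' @param output_dir Optional directory to write the cohort to.
#' @return List with `runs` (list of `bold_run`), `truth`, `atlas`.
#' @export
simulate_cohort <- function(cfg, atlas = NULL, output_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(atlas)) atlas <- make_default_atlas(seed = cfg$seed)
  truth <- simulate_network_timecourses(cfg, atlas)
  demo <- with_seed(child_seed(cfg$seed, 999983), {
    list(age = round(stats::runif(cfg$n_subjects, 23, 75)),
         sex = rep_len(c("F", "M"), cfg$n_subjects))
  })
  runs <- lapply(seq_len(cfg$n_subjects), function(i) {
    r <- simulate_subject(cfg, atlas, truth, i)
    r$age <- demo$age[i]
    r$sex <- demo$sex[i]
    r
  })
  truth$subject_seeds <- vapply(runs, function(r) r$seed, integer(1))
  if (!is.null(output_dir)) write_cohort(runs, atlas, truth, cfg, output_dir)
  list(runs = runs, truth = truth, atlas = atlas)
}
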