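# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

tiny_atlas <- function() cached("tiny_atlas",
  make_default_atlas(c(16, 16, 12), c(4, 4, 5), seed = 1L))

tiny_cfg <- function(n_subjects = 2, n_volumes = 100, snr = 1, seed = 11L)
  sim_config(n_subjects = n_subjects, n_volumes = n_volumes, snr = snr,
             seed = seed)

tiny_cohort <- function() cached("tiny_cohort",
  simulate_cohort(tiny_cfg(), tiny_atlas()))

# hand-built minimal run with known injected components
handmade_run <- function(n_volumes = 80, tr = 2, seed = 5L,
                         global_course = NULL) {
  d <- c(8, 8, 6)
  brain <- array(TRUE, d)
  wm <- array(FALSE, d); wm[2:3, 2:3, 2:3] <- TRUE
  csf <- array(FALSE, d); csf[6:7, 6:7, 4:5] <- TRUE
  gm <- brain & !wm & !csf
  set.seed(seed)
  dat <- array(rnorm(prod(d) * n_volumes), c(d, n_volumes))
  if (!is.null(global_course)) {
    for (t in seq_len(n_volumes))
      dat[, , , t] <- dat[, , , t] + global_course[t]
  }
  motion <- matrix(rnorm(n_volumes * 6, sd = 0.1), n_volumes, 6)
  structure(list(data = dat, tr_seconds = tr, voxel_size_mm = c(4, 4, 5),
                 brain_mask = brain, gm_mask = gm, wm_mask = wm,
                 csf_mask = csf, motion = motion, subject_id = "hand",
                 age = 40, sex = "F"),
            class = "bold_run")
}

# two well-separated Gaussian blobs in the plane
two_blobs <- function(n_per = 15, sep = 20, seed = 3L) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n_per), rnorm(n_per)),
             cbind(rnorm(n_per) + sep, rnorm(n_per)))
  list(X = X, truth = rep(1:2, each = n_per))
}

four_blobs <- function(n_per = 20, sep = 12, seed = 4L) {
  set.seed(seed)
  ctrs <- rbind(c(0, 0), c(sep, 0), c(0, sep), c(sep, sep))
  X <- do.call(rbind, lapply(1:4, function(k)
    cbind(rnorm(n_per) + ctrs[k, 1], rnorm(n_per) + ctrs[k, 2])))
  list(X = X, truth = rep(1:4, each = n_per))
}

# fraction of periodogram power inside [lo, hi] Hz
band_power_fraction <- function(x, tr, lo, hi) {
  n <- length(x)
  x <- x - mean(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) / (n * tr)
  fold <- pmin(f, 1 / tr - f)
  sum(p[fold >= lo & fold <= hi]) / sum(p)
}

# exhaustive 2-means: best bipartition by within-cluster sum of squares
brute_two_means <- function(X) {
  n <- nrow(X)
  best <- NULL; best_cost <- Inf
  for (code in 1:(2^(n - 1) - 1)) { # point 1 fixed in cluster 1
    lab <- c(1L, as.integer(bitwAnd(bitwShiftR(code, 0:(n - 2)), 1L)) + 1L)
    cost <- 0
    for (k in 1:2) {
      sel <- X[lab == k, , drop = FALSE]
      if (nrow(sel) == 0) { cost <- Inf; break }
      ctr <- colMeans(sel)
      cost <- cost + sum(sweep(sel, 2, ctr)^2)
    }
    if (cost < best_cost) { best_cost <- cost; best <- lab }
  }
  list(labels = best, cost = best_cost)
}

# agreement of two labelings up to permutation of labels
same_up_to_permutation <- function(a, b, c) {
  perms <- all_permutations(c)
  any(vapply(seq_len(nrow(perms)), function(i)
    all(perms[i, ][a] == b), logical(1)))
}

all_permutations <- function(c) {
  if (c == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(c - 1)
  do.call(rbind, lapply(seq_len(nrow(sub)), function(i)
    t(vapply(seq_len(c), function(pos)
      as.integer(append(sub[i, ], c, after = pos - 1)), integer(c)))))
}
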