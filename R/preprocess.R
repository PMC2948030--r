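## Temporal and spatial conditioning of BOLD runs.

# Cache of T x T temporal operator matrices, keyed by (length, TR, band).
.op_cache <- new.env(parent = emptyenv())

#' Remove a linear trend (and intercept) from a time series
#'
#' Fits an ordinary least-squares line against the time index and returns the
#' residuals, so the output has zero mean and zero slope.
#'
#' @param ts Numeric vector, or a matrix with one series per column.
#' @return Object of the same shape with the linear trend removed.
#' @export
#' @examples
#' detrend_linear(c(1, 2, 3, 4))  # pure ramp -> all zeros
detrend_linear <- function(ts) {
  n <- if (is.matrix(ts)) nrow(ts) else length(ts)
  stop_if_not(n >= 2, "need at least 2 time points to detrend",
              class = "fcparcel_size_error")
  P <- detrend_projector(n)
  if (is.matrix(ts)) P %*% ts else drop(P %*% ts)
}

detrend_projector <- function(n) {
  key <- sprintf("detrend_%d", n)
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  X <- cbind(1, seq_len(n))
  P <- diag(n) - X %*% solve(crossprod(X), t(X))
  .op_cache[[key]] <- P
  P
}

#' Zero-phase band-pass filter for BOLD time series
#'
#' Second-order Butterworth applied forward and backward
#' ([signal::filtfilt()]), giving zero phase shift and fourth-order effective
#' roll-off. A band edge at 0 or at Nyquist degrades gracefully to a low- or
#' high-pass filter.
#'
#' @param ts Numeric vector, or a matrix with one series per column.
#' @param tr_seconds Repetition time in seconds (sampling interval).
#' @param low_hz,high_hz Pass-band edges in Hz; `0 <= low < high <= Nyquist`.
#' @return Filtered series, same shape as `ts`.
#' @export
bandpass <- function(ts, tr_seconds, low_hz = 0.01, high_hz = 0.1) {
  n <- if (is.matrix(ts)) nrow(ts) else length(ts)
  M <- bandpass_operator(n, tr_seconds, low_hz, high_hz)
  if (is.matrix(ts)) M %*% ts else drop(M %*% ts)
}

# The filtfilt operation is linear in its input, so it is represented exactly
# by a T x T matrix (built once per length/TR/band and cached); this lets the
# whole brain be filtered with one matrix product.
bandpass_operator <- function(n, tr_seconds, low_hz, high_hz) {
  stop_if_not(n >= 12, "series too short to band-pass filter",
              class = "fcparcel_size_error")
  nyq <- 1 / (2 * tr_seconds)
  stop_if_not(low_hz >= 0 && high_hz > low_hz && high_hz <= nyq,
              sprintf("invalid band [%g, %g] Hz for TR %g s (Nyquist %g Hz)",
                      low_hz, high_hz, tr_seconds, nyq),
              class = "fcparcel_config_error")
  key <- sprintf("bp_%d_%g_%g_%g", n, tr_seconds, low_hz, high_hz)
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  bf <- if (low_hz <= 0) {
    signal::butter(2, high_hz / nyq, type = "low")
  } else if (high_hz >= nyq) {
    signal::butter(2, low_hz / nyq, type = "high")
  } else {
    signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  }
  # The filter is applied to the mean-centered series (a band-pass has zero
  # DC gain, and centering kills it exactly rather than leaving edge
  # transients) with mirror padding at both ends to suppress boundary
  # transients of the forward-backward pass.
  npad <- n - 1
  pad_idx <- c((npad + 1):2, seq_len(n), (n - 1):(n - npad))
  mid <- npad + seq_len(n)
  M <- vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1
    e <- e - mean(e)
    signal::filtfilt(bf, e[pad_idx])[mid]
  }, numeric(n))
  .op_cache[[key]] <- M
  M
}

#' Gaussian spatial smoothing with mask renormalization
#'
#' Separable Gaussian convolution with per-axis sigma
#' `fwhm / (2 sqrt(2 log 2)) / voxel_size`, renormalized by the smoothed mask
#' so that signal is not diluted at mask borders. Values outside the mask are
#' set to zero. `fwhm_mm = 0` is the identity (within the mask).
#'
#' @param volume4d 4-D array (x, y, z, t) or a single 3-D volume.
#' @param fwhm_mm Kernel full width at half maximum, millimetres.
#' @param voxel_size_mm Length-3 voxel dimensions in millimetres.
#' @param mask 3-D logical/0-1 array; smoothing is confined to it.
#' @return Array of the same shape as `volume4d`.
#' @export
smooth_gaussian <- function(volume4d, fwhm_mm, voxel_size_mm, mask = NULL) {
  stop_if_not(fwhm_mm >= 0, "fwhm_mm must be nonnegative",
              class = "fcparcel_value_error")
  nd <- length(dim(volume4d))
  stop_if_not(nd %in% c(3, 4), "expected a 3-D or 4-D array",
              class = "fcparcel_value_error")
  d3 <- dim(volume4d)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d3)
  mask <- array(as.logical(mask), d3)
  if (fwhm_mm == 0) {
    out <- volume4d
    if (nd == 3) out[!mask] <- 0
    else out <- sweep_mask4(out, mask)
    return(out)
  }
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  Ks <- lapply(seq_len(3), function(ax) gauss_conv_matrix(d3[ax], sigma[ax]))
  m_num <- array(as.numeric(mask), d3)
  sm_mask <- conv_separable(m_num, Ks)
  denom <- ifelse(sm_mask > 0 & mask, sm_mask, 1)
  smooth_one <- function(v) {
    out <- conv_separable(v * m_num, Ks) / denom
    out[!mask] <- 0
    out
  }
  if (nd == 3) return(smooth_one(volume4d))
  out <- volume4d
  for (t in seq_len(dim(volume4d)[4])) out[, , , t] <- smooth_one(volume4d[, , , t])
  out
}

sweep_mask4 <- function(arr4, mask) {
  nt <- dim(arr4)[4]
  mrep <- array(rep(mask, nt), dim(arr4))
  arr4 * mrep
}

gauss_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(4 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1 & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[off + r + 1]
  }
  K
}

# Apply axis-wise convolution matrices to a 3-D array.
conv_separable <- function(vol, Ks) {
  d <- dim(vol)
  a <- matrix(vol, d[1]) # d1 x (d2 d3)
  a <- Ks[[1]] %*% a
  a <- array(a, d)
  a <- aperm(a, c(2, 1, 3))
  m <- matrix(a, d[2])
  m <- Ks[[2]] %*% m
  a <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  a <- aperm(a, c(3, 1, 2))
  m <- matrix(a, d[3])
  m <- Ks[[3]] %*% m
  aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Preprocess a BOLD run
#'
#' Applies, in order: optional Gaussian spatial smoothing (seed-connectivity
#' branch only), per-voxel linear detrending, and zero-phase band-pass
#' filtering. The parcellation branch conventionally runs with
#' `smooth = FALSE`.
#'
#' @param run A `bold_run` (see [simulate_subject()] or [read_bold()]).
#' @param fwhm_mm Smoothing kernel FWHM in millimetres (default 8).
#' @param band_hz Length-2 pass band in Hz (default `c(0.01, 0.1)`).
#' @param smooth Apply spatial smoothing? Default `TRUE`.
#' @return The run with `data` replaced by its conditioned version.
#' @export
preprocess_run <- function(run, fwhm_mm = 8, band_hz = c(0.01, 0.1),
                           smooth = TRUE) {
  stopifnot(inherits(run, "bold_run"))
  check_finite(run$data, "BOLD data")
  d <- dim(run$data)
  dat <- run$data
  if (smooth && fwhm_mm > 0) {
    dat <- smooth_gaussian(dat, fwhm_mm, run$voxel_size_mm, run$brain_mask)
  }
  nt <- d[4]
  Op <- bandpass_operator(nt, run$tr_seconds, band_hz[1], band_hz[2]) %*%
    detrend_projector(nt)
  Y <- t(matrix(dat, prod(d[1:3]), nt)) # time x voxels
  Y <- Op %*% Y
  run$data <- array(t(Y), d)
  check_finite(run$data, "preprocessed BOLD data")
  run$preprocessed <- list(fwhm_mm = if (smooth) fwhm_mm else 0,
                           band_hz = band_hz, smooth = smooth)
  run
}
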