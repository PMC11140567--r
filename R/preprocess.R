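# Functional preprocessing: volume discard, motion QC, nuisance regression,
# ideal bandpass, Gaussian smoothing.

#' Discard initial volumes
#'
#' Drops the first `n` volumes (magnetization equilibration / adaptation
#' period).
#'
#' @param bold a [bold4d].
#' @param n number of leading volumes to drop (default 10).
#' @return A [bold4d] with `n` fewer volumes.
#' @export
discard_initial_volumes <- function(bold, n = 10L) {
  stopifnot(inherits(bold, "bold4d"))
  nt <- dim(bold$data)[4]
  if (n < 0L) stop("n must be >= 0")
  if (n >= nt)
    stop("cannot discard ", n, " volumes from a ", nt, "-volume series")
  if (n == 0L) return(bold)
  bold4d(bold$data[, , , -seq_len(n), drop = FALSE], bold$affine, bold$tr_s)
}

#' Motion quality control
#'
#' A subject fails if any translation axis strictly exceeds `max_trans_mm` in
#' absolute value, or any rotation axis strictly exceeds `max_rot_deg`.
#' Boundary values (exactly at the threshold) pass.
#'
#' @param motion time x 6 matrix: translations (mm) then rotations (degrees).
#' @param max_trans_mm,max_rot_deg exclusion thresholds (defaults 2 mm, 2
#'   degrees).
#' @return A list with `pass` (logical), per-axis maxima `max_trans` and
#'   `max_rot`, and `offending` axis names (empty if pass).
#' @export
motion_qc <- function(motion, max_trans_mm = 2, max_rot_deg = 2) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion must have 6 columns, found ", ncol(motion))
  stopifnot(max_trans_mm > 0, max_rot_deg > 0)
  axes <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  mx <- apply(abs(motion), 2, max)
  names(mx) <- axes
  offending <- axes[c(mx[1:3] > max_trans_mm, mx[4:6] > max_rot_deg)]
  list(pass = length(offending) == 0L,
       max_trans = mx[1:3], max_rot = mx[4:6],
       offending = offending)
}

# time x voxel matrix view of the 4D array (copy)
bold_matrix <- function(bold) {
  d <- dim(bold$data)
  t(matrix(bold$data, prod(d[1:3]), d[4]))
}

matrix_bold <- function(m, like) {
  bold4d(array(t(m), c(dim(like$data)[1:3], nrow(m))),
         like$affine, like$tr_s)
}

#' Regress out nuisance signals
#'
#' Ordinary least-squares regression of every voxel series on an intercept
#' plus the 8 confounds (6 motion parameters, white matter, CSF); the
#' residuals are returned. Residuals are orthogonal to every confound column.
#'
#' @param bold a [bold4d].
#' @param confounds a [confound_set] (or time x 8 matrix) with the same time
#'   length as `bold`.
#' @return A [bold4d] of residuals.
#' @export
regress_nuisance <- function(bold, confounds) {
  stopifnot(inherits(bold, "bold4d"))
  conf <- as.matrix(confounds)
  nt <- dim(bold$data)[4]
  if (nrow(conf) != nt)
    stop("confound length ", nrow(conf), " != BOLD time length ", nt)
  X <- cbind(intercept = 1, conf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient confound design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  Y <- bold_matrix(bold)
  matrix_bold(qr.resid(qx, Y), bold)
}

#' Ideal temporal bandpass filter
#'
#' Frequency-domain (discrete Fourier) filter: bins with frequency inside
#' `[low_hz, high_hz]` are retained, all others (including DC) are zeroed,
#' and the series is inverse-transformed. Exactly idempotent.
#'
#' @param bold a [bold4d].
#' @param low_hz,high_hz passband edges in Hz (defaults 0.01 and 0.08).
#' @return A filtered [bold4d].
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(bold, "bold4d"))
  if (high_hz <= low_hz) stop("high_hz must exceed low_hz")
  nyquist <- 1 / (2 * bold$tr_s)
  if (high_hz >= nyquist)
    stop(sprintf("high_hz (%.4g) must be below the Nyquist frequency %.4g Hz",
                 high_hz, nyquist))
  Y <- bold_matrix(bold)
  nt <- nrow(Y)
  k <- 0:(nt - 1)
  f <- pmin(k, nt - k) / (nt * bold$tr_s)
  keep <- f >= low_hz & f <= high_hz & k != 0
  Fy <- stats::mvfft(Y)
  Fy[!keep, ] <- 0
  matrix_bold(Re(stats::mvfft(Fy, inverse = TRUE)) / nt, bold)
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve an array along one axis with a centered 1D kernel, zero-padded
conv_axis <- function(a, k, axis) {
  if (length(k) == 1L) return(a)
  d <- dim(a)
  perm <- c(axis, setdiff(seq_along(d), axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, dp[1])
  out <- matrix(0, nrow(m), ncol(m))
  r <- (length(k) - 1L) / 2L
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(dp[1]) + off
    ok <- src >= 1L & src <= dp[1]
    if (any(ok))
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
  }
  dim(out) <- dp
  aperm(out, order(perm))
}

#' Gaussian spatial smoothing
#'
#' Separable 3D Gaussian convolution with per-axis sigma =
#' `fwhm_mm / (2 sqrt(2 ln 2))`, converted to voxels through the voxel size
#' (anisotropic voxels honored per axis). Edges are zero-padded with a
#' sum-normalized kernel, so constants are preserved away from edges.
#'
#' `smooth_volume()` smooths a single 3D array; `smooth_bold()` applies the
#' same kernel to every volume of a 4D series.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm full width at half maximum of the kernel, in mm (default 6).
#' @param voxel_mm length-3 voxel size in mm.
#' @return Smoothed array / [bold4d].
#' @export
smooth_volume <- function(vol, fwhm_mm = 6, voxel_mm = c(3, 3, 3)) {
  stopifnot(fwhm_mm >= 0, length(dim(vol)) >= 3L)
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  for (ax in 1:3)
    vol <- conv_axis(vol, gaussian_kernel_1d(sigma_vox[ax]), ax)
  vol
}

#' @rdname smooth_volume
#' @param bold a [bold4d].
#' @export
smooth_bold <- function(bold, fwhm_mm = 6) {
  stopifnot(inherits(bold, "bold4d"))
  if (fwhm_mm == 0) return(bold)
  vs <- voxel_sizes(bold$affine)
  # treating time as a trailing axis lets one pass smooth all volumes at once
  bold4d(smooth_volume(bold$data, fwhm_mm, vs), bold$affine, bold$tr_s)
}

#' Full preprocessing chain
#'
#' discard -> nuisance regression -> bandpass -> smooth (default), or with
#' `bandpass_last = TRUE`: discard -> regress -> smooth -> bandpass. The
#' confounds are trimmed by the same `n_discard` leading samples as the BOLD
#' series.
#'
#' @param bold a [bold4d] (raw, full length).
#' @param confounds a [confound_set] of the raw length.
#' @param n_discard leading volumes to drop (default 10).
#' @param low_hz,high_hz bandpass edges (defaults 0.01, 0.08 Hz).
#' @param fwhm_mm smoothing kernel FWHM (default 6 mm).
#' @param bandpass_last move the temporal filter after smoothing.
#' @return An analysis-ready [bold4d].
#' @export
preprocess_bold <- function(bold, confounds, n_discard = 10L,
                            low_hz = 0.01, high_hz = 0.08, fwhm_mm = 6,
                            bandpass_last = FALSE) {
  conf <- as.matrix(confounds)
  if (n_discard > 0L) {
    if (n_discard >= nrow(conf)) stop("n_discard exceeds confound length")
    conf <- conf[-seq_len(n_discard), , drop = FALSE]
  }
  out <- discard_initial_volumes(bold, n_discard)
  out <- regress_nuisance(out, conf)
  if (bandpass_last) {
    out <- smooth_bold(out, fwhm_mm)
    out <- bandpass(out, low_hz, high_hz)
  } else {
    out <- bandpass(out, low_hz, high_hz)
    out <- smooth_bold(out, fwhm_mm)
  }
  out
}
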