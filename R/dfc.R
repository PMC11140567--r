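# Seed-to-voxel sliding-window correlation, Fisher z, and per-voxel
# variability (SD over windows) maps.

#' Sliding-window specification
#'
#' @param length_tr window length in TRs (50 TRs = 100 s at TR 2 s).
#' @param step_tr slide step in TRs (default 1).
#' @param taper `"hamming"` (observation weights inside the correlation) or
#'   `"rectangular"`.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_tr = 50L, step_tr = 1L, taper = "hamming") {
  stopifnot(length_tr >= 1L, step_tr >= 1L)
  taper <- match.arg(taper, c("hamming", "rectangular"))
  structure(list(length_tr = as.integer(length_tr),
                 step_tr = as.integer(step_tr), taper = taper),
            class = "window_spec")
}

#' Number of sliding windows
#'
#' Window k (0-based) covers samples `[k*step, k*step + length)`; the count
#' is `floor((n - length)/step) + 1`. 200 analyzed volumes with a 50-TR
#' window sliding by 1 TR give 151 windows.
#'
#' @param n_timepoints length of the analyzed series.
#' @param window a [window_spec].
#' @return Integer window count.
#' @export
count_windows <- function(n_timepoints, window) {
  stopifnot(inherits(window, "window_spec"))
  if (window$length_tr > n_timepoints)
    stop("window length ", window$length_tr,
         " exceeds series length ", n_timepoints)
  as.integer((n_timepoints - window$length_tr) %/% window$step_tr + 1L)
}

#' Hamming taper weights
#'
#' `w[i] = 0.54 - 0.46 cos(2 pi i / (L - 1))`, i = 0..L-1; strictly positive,
#' symmetric, endpoints 0.08.
#'
#' @param length window length L (>= 2).
#' @return Numeric weight vector of length L.
#' @export
hamming_taper <- function(length) {
  if (length < 2L) stop("taper length must be >= 2")
  i <- 0:(length - 1)
  0.54 - 0.46 * cos(2 * pi * i / (length - 1))
}

window_weights <- function(window) {
  switch(window$taper,
         hamming = hamming_taper(window$length_tr),
         rectangular = rep(1, window$length_tr))
}

#' Weighted Pearson correlation
#'
#' Pearson correlation under observation weights: weighted means, variances
#' and covariance with weights `w`. Zero weighted variance in either series
#' makes the correlation undefined; `NA` is returned.
#'
#' @param x,y numeric series of equal length.
#' @param w non-negative weights, `sum(w) > 0`.
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
weighted_correlation <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w))
    stop("x, y and w must have equal lengths")
  sw <- sum(w)
  if (sw <= 0) stop("sum of weights must be positive")
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  if (vx <= 0 || vy <= 0) return(NA_real_)
  cv <- sum(w * (x - mx) * (y - my)) / sw
  max(-1, min(1, cv / sqrt(vx * vy)))
}

#' Fisher z transform
#'
#' `atanh(r)` with `|r|` clipped to `1 - 1e-7` so perfect correlations map to
#' a large finite value instead of infinity.
#'
#' @param r correlation value(s), `|r| <= 1` (small numerical overshoot
#'   tolerated).
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE))
    stop("|r| > 1: not a correlation")
  clip <- 1 - 1e-7
  atanh(pmin(pmax(r, -clip), clip))
}

#' Mean time series over a seed sphere
#'
#' Unweighted mean across the seed's voxels at each time point.
#'
#' @param bold a [bold4d].
#' @param voxels voxel index matrix from [build_sphere_mask()].
#' @return Numeric series of length `dim(bold$data)[4]`.
#' @export
extract_seed_timeseries <- function(bold, voxels) {
  stopifnot(inherits(bold, "bold4d"))
  if (is.null(dim(voxels)) || nrow(voxels) == 0L)
    stop("empty seed voxel set")
  d <- dim(bold$data)
  lin <- attr(voxels, "linear")
  if (is.null(lin))
    lin <- voxels[, 1] + (voxels[, 2] - 1L) * d[1] +
      (voxels[, 3] - 1L) * d[1] * d[2]
  if (any(lin < 1L | lin > prod(d[1:3])))
    stop("seed voxels outside the grid")
  Y <- matrix(bold$data, prod(d[1:3]), d[4])[lin, , drop = FALSE]
  colMeans(Y)
}

#' dFC variance map for one subject and seed
#'
#' For every in-mask voxel: taper-weighted Pearson correlation with the seed
#' series inside each sliding window, Fisher z transform, then the sample
#' standard deviation (n-1 denominator) of the z values over windows.
#'
#' @param bold an analysis-ready [bold4d] (post preprocessing).
#' @param seed_series seed mean time series, same length as the BOLD series.
#' @param window a [window_spec]; at least 2 windows must fit.
#' @param mask a [brain_mask] on the same grid.
#' @param seed_name,subject_id labels stored on the result.
#' @param standardize z-score the SD values across in-mask voxels before
#'   returning (a common toolbox behavior ahead of group statistics;
#'   default `FALSE`, the untouched SD map).
#' @return An object of class `dfc_map`: list with `data` (3D array, `NA`
#'   outside the mask), `seed_name`, `subject_id`, `window`, `n_windows`,
#'   `affine`.
#' @export
dfc_variance_map <- function(bold, seed_series, window, mask,
                             seed_name = "seed", subject_id = "subject",
                             standardize = FALSE) {
  stopifnot(inherits(bold, "bold4d"), inherits(mask, "brain_mask"))
  d <- dim(bold$data)
  check_same_grid(d, bold$affine, dim(mask$data), mask$affine,
                  "BOLD and mask")
  nt <- d[4]
  if (length(seed_series) != nt)
    stop("seed series length ", length(seed_series),
         " != BOLD time length ", nt)
  K <- count_windows(nt, window)
  if (K < 2L) stop("need at least 2 windows, got ", K)
  w <- window_weights(window)
  L <- window$length_tr
  starts <- (seq_len(K) - 1L) * window$step_tr  # 0-based

  # window-weight design: column k holds the taper at that window's span
  W <- matrix(0, nt, K)
  for (k in seq_len(K)) W[starts[k] + seq_len(L), k] <- w
  sw <- sum(w)

  lin <- which(mask$data)
  Y <- matrix(bold$data, prod(d[1:3]), nt)[lin, , drop = FALSE]
  # center to keep the one-pass weighted moments well conditioned
  x <- as.numeric(seed_series) - mean(seed_series)
  Y <- t(Y) - rep(colMeans(t(Y)), each = nt)  # nt x V, column-centered

  mx <- drop(crossprod(W, x)) / sw                 # K
  my <- crossprod(W, Y) / sw                       # K x V
  vx <- drop(crossprod(W, x^2)) / sw - mx^2        # K
  vy <- crossprod(W, Y^2) / sw - my^2              # K x V
  cv <- crossprod(W, Y * x) / sw - mx * my         # K x V
  vx <- pmax(vx, 0)
  vy[vy < 0] <- 0
  denom <- sqrt(vx * vy)                           # recycles vx down columns
  r <- cv / denom
  r[denom == 0] <- NA
  r[r > 1] <- 1
  r[r < -1] <- -1
  z <- fisher_z(r)

  mz <- colMeans(z)
  sdz <- sqrt(pmax(colSums(z^2) - K * mz^2, 0) / (K - 1))
  if (standardize)
    sdz <- (sdz - mean(sdz, na.rm = TRUE)) / stats::sd(sdz, na.rm = TRUE)
  out <- array(NA_real_, d[1:3])
  out[lin] <- sdz
  structure(list(data = out, seed_name = seed_name, subject_id = subject_id,
                 window = window, n_windows = K, affine = bold$affine),
            class = "dfc_map")
}

#' @export
print.dfc_map <- function(x, ...) {
  cat(sprintf("<dfc_map> subject %s, seed %s, %d windows (length %d, step %d, %s)\n",
              x$subject_id, x$seed_name, x$n_windows, x$window$length_tr,
              x$window$step_tr, x$window$taper))
  invisible(x)
}
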