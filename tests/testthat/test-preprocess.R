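test_that("initial volume discard shortens the series and checks bounds", {
  b <- toy_bold(c(3, 3, 3), 210)
  out <- discard_initial_volumes(b, 10)
  expect_equal(dim(out$data)[4], 200L)
  expect_equal(out$data[, , , 1], b$data[, , , 11])
  expect_identical(discard_initial_volumes(b, 0), b)
  short <- toy_bold(c(3, 3, 3), 5)
  expect_error(discard_initial_volumes(short, 10), "5-volume")
})

test_that("motion QC uses strict exceedance and names offending axes", {
  zero <- matrix(0, 50, 6)
  expect_true(motion_qc(zero)$pass)

  m <- zero
  m[17, 2] <- 2.5
  qc <- motion_qc(m)
  expect_false(qc$pass)
  expect_equal(qc$offending, "trans_y")
  expect_equal(unname(qc$max_trans["trans_y"]), 2.5)

  m <- zero
  m[3, 5] <- -2.4
  expect_equal(motion_qc(m)$offending, "rot_y")

  boundary <- zero
  boundary[1, 1] <- 2.0
  boundary[2, 6] <- -2.0
  expect_true(motion_qc(boundary)$pass)

  expect_error(motion_qc(zero[, 1:5]), "6 columns")
})

make_confounds <- function(nt, seed = 3) {
  set.seed(seed)
  confound_set(matrix(rnorm(nt * 6), nt), rnorm(nt), rnorm(nt))
}

test_that("nuisance regression removes confounds exactly", {
  nt <- 60
  conf <- make_confounds(nt)
  d <- c(3, 2, 2)
  arr <- array(rnorm(prod(d) * nt), c(d, nt))
  # voxel (1,1,1) is a pure copy of motion regressor 4
  arr[1, 1, 1, ] <- conf[, 4]
  b <- bold4d(arr, diag(c(3, 3, 3, 1)), 2)
  res <- regress_nuisance(b, conf)
  expect_lt(max(abs(res$data[1, 1, 1, ])), 1e-10)

  # residuals orthogonal to every confound column
  Y <- t(matrix(res$data, prod(d), nt))
  expect_lt(max(abs(crossprod(as.matrix(conf), Y))), 1e-8)
  # and to the intercept
  expect_lt(max(abs(colSums(Y))), 1e-8)
})

test_that("series orthogonal to the confounds pass through unchanged", {
  nt <- 40
  set.seed(8)
  conf <- confound_set(matrix(rnorm(nt * 6), nt), rnorm(nt), rnorm(nt))
  X <- cbind(1, as.matrix(conf))
  y <- rnorm(nt)
  y <- y - X %*% solve(crossprod(X), crossprod(X, y))  # project out
  arr <- array(rep(y, each = 8), c(2, 2, 2, nt))
  arr <- aperm(array(y, c(nt, 2, 2, 2)), c(2, 3, 4, 1))
  b <- bold4d(arr, diag(c(3, 3, 3, 1)), 2)
  res <- regress_nuisance(b, conf)
  expect_equal(res$data, b$data, tolerance = 1e-10)
})

test_that("regression residuals match a normal-equations oracle", {
  nt <- 80
  conf <- make_confounds(nt, seed = 11)
  b <- toy_bold(c(4, 3, 2), nt, seed = 12)
  res <- regress_nuisance(b, conf)
  X <- cbind(1, as.matrix(conf))
  beta_hat <- solve(crossprod(X))
  for (vox in list(c(1, 1, 1), c(4, 3, 2), c(2, 2, 1))) {
    y <- b$data[vox[1], vox[2], vox[3], ]
    r <- y - X %*% (beta_hat %*% crossprod(X, y))
    expect_equal(res$data[vox[1], vox[2], vox[3], ], as.numeric(r),
                 tolerance = 1e-8)
  }
  # idempotence: residuals are already orthogonal to the design
  res2 <- regress_nuisance(res, conf)
  expect_equal(res2$data, res$data, tolerance = 1e-10)
})

test_that("duplicated confounds raise a rank-deficiency error", {
  nt <- 30
  set.seed(4)
  motion <- matrix(rnorm(nt * 6), nt)
  motion[, 2] <- motion[, 1]
  conf <- confound_set(motion, rnorm(nt), rnorm(nt))
  b <- toy_bold(c(2, 2, 2), nt)
  expect_error(regress_nuisance(b, conf), "collinear")
})

test_that("ideal bandpass keeps the passband and kills the stopband", {
  nt <- 200
  tr <- 2
  t_s <- (0:(nt - 1)) * tr
  in_band <- sin(2 * pi * 0.05 * t_s)
  out_band <- sin(2 * pi * 0.2 * t_s)
  mk <- function(y) bold4d(array(rep(y, each = 1), c(1, 1, 1, nt)),
                           diag(c(3, 3, 3, 1)), tr)
  kept <- bandpass(mk(in_band))$data[1, 1, 1, ]
  expect_equal(sqrt(mean(kept^2)), sqrt(mean(in_band^2)), tolerance = 0.01)
  removed <- bandpass(mk(out_band))$data[1, 1, 1, ]
  expect_lt(sqrt(mean(removed^2)), 0.01 * sqrt(mean(out_band^2)))
  # DC removal
  flat <- bandpass(mk(rep(7, nt)))$data
  expect_lt(max(abs(flat)), 1e-10)
})

test_that("bandpass is an exact projection and validates its band", {
  b <- toy_bold(c(2, 2, 2), 100)
  once <- bandpass(b)
  twice <- bandpass(once)
  expect_equal(twice$data, once$data, tolerance = 1e-12)
  expect_error(bandpass(b, 0.08, 0.01), "exceed")
  expect_error(bandpass(b, 0.01, 0.3), "Nyquist")
})

test_that("Gaussian smoothing has the right impulse response", {
  d <- c(21, 21, 21)
  imp <- array(0, d)
  imp[11, 11, 11] <- 1
  sm <- smooth_volume(imp, fwhm_mm = 6, voxel_mm = c(3, 3, 3))
  expect_equal(sum(sm), 1, tolerance = 1e-3)  # mass preserved
  prof <- sm[, 11, 11]
  half <- max(prof) / 2
  # linear interpolation of the half-maximum crossings, in mm
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  xlo <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  xhi <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm_est <- (xhi - xlo) * 3
  expect_equal(fwhm_est, 6, tolerance = 0.05)
  # symmetry and anisotropic voxel handling
  expect_equal(sm[, 11, 11], sm[11, , 11])
  sm_aniso <- smooth_volume(imp, 6, voxel_mm = c(3, 6, 3))
  expect_gt(sm_aniso[11, 12, 11], 0)
  expect_lt(sum(sm_aniso[11, , 11] > 1e-6), sum(sm[11, , 11] > 1e-6))
})

test_that("smoothing identity and constant invariance", {
  b <- toy_bold(c(8, 8, 8), 5)
  expect_identical(smooth_bold(b, 0), b)
  const <- bold4d(array(3, c(15, 15, 15, 2)), diag(c(3, 3, 3, 1)), 2)
  sm <- smooth_bold(const, 6)
  expect_equal(sm$data[8, 8, 8, 1], 3, tolerance = 1e-10)  # interior
  expect_equal(sm$data[6:10, 6:10, 6:10, 2],
               const$data[6:10, 6:10, 6:10, 2], tolerance = 1e-6)
})

test_that("the preprocessing chain composes and the order switch matters", {
  cfg <- tiny_config(rng_seed = 21)
  sub <- simulate_subject_bold(cfg, 1, 77)
  conf <- confound_set(sub$motion, sub$nuisance[, 1], sub$nuisance[, 2])
  pre <- preprocess_bold(sub$bold, conf)
  expect_equal(dim(pre$data)[4], 200L)
  pre2 <- preprocess_bold(sub$bold, conf, bandpass_last = TRUE)
  expect_equal(dim(pre2$data), dim(pre$data))
  expect_gt(max(abs(pre2$data - pre$data)), 0)  # orders differ
  # smoothing and the ideal filter commute up to edge effects only; both
  # orders leave the passband structure intact
  expect_equal(mean(pre2$data^2), mean(pre$data^2), tolerance = 0.2)
})
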