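test_that("window arithmetic matches the closed form", {
  expect_equal(count_windows(200, window_spec(50, 1)), 151L)
  expect_equal(count_windows(50, window_spec(50, 1)), 1L)
  expect_equal(count_windows(10, window_spec(3, 2)), 4L)
  # enumeration oracle: starts k*step with k*step + length <= n
  for (n in c(17, 60)) for (L in c(3, 8)) for (s in 1:3) {
    starts <- seq(0, n - L, by = s)
    expect_equal(count_windows(n, window_spec(L, s)), length(starts))
  }
  expect_error(count_windows(10, window_spec(11, 1)), "exceeds")
})

test_that("Hamming taper has the closed-form shape", {
  for (L in c(4, 50, 51)) {
    w <- hamming_taper(L)
    expect_equal(w[1], 0.08)
    expect_equal(w[L], 0.08)
    expect_equal(w, rev(w))
    expect_true(all(w > 0))
  }
  expect_equal(hamming_taper(51)[26], 1.0)  # odd length center
  expect_equal(hamming_taper(50), 0.54 - 0.46 * cos(2 * pi * (0:49) / 49))
  expect_error(hamming_taper(1), ">= 2")
})

test_that("weighted correlation agrees with a two-pass oracle", {
  w4 <- hamming_taper(4)
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 4)
  expect_equal(weighted_correlation(x, y, w4), oracle_weighted_cor(x, y, w4),
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 10))
    y <- rnorm(n) + runif(1, -2, 2) * x
    w <- runif(n)
    expect_equal(weighted_correlation(x, y, w),
                 oracle_weighted_cor(x, y, w), tolerance = 1e-12)
  }
})

test_that("weighted correlation endpoints and degeneracies", {
  w <- hamming_taper(10)
  x <- rnorm(10)
  expect_equal(weighted_correlation(x, x, w), 1)
  expect_equal(weighted_correlation(x, -x, w), -1)
  expect_equal(weighted_correlation(x, 2 * x + 5, w), 1)
  expect_true(is.na(weighted_correlation(x, rep(1, 10), w)))
  expect_error(weighted_correlation(x, x[1:5], w), "equal lengths")
  expect_error(weighted_correlation(x, x, rep(0, 10)), "positive")
})

test_that("Fisher z is atanh with clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_true(is.finite(fisher_z(-1)))
  expect_error(fisher_z(1.01), "not a correlation")
})

test_that("seed series is the brute-force voxel mean", {
  b <- toy_bold(c(5, 4, 3), 30, seed = 9)
  one <- matrix(c(2, 3, 1), 1)
  expect_equal(extract_seed_timeseries(b, one), b$data[2, 3, 1, ])
  # cancellation
  b2 <- b
  b2$data[1, 1, 1, ] <- sin(1:30)
  b2$data[2, 1, 1, ] <- -sin(1:30)
  two <- rbind(c(1, 1, 1), c(2, 1, 1))
  expect_equal(extract_seed_timeseries(b2, two), rep(0, 30))
  # 33-voxel sphere vs explicit loop
  mask <- toy_mask(c(5, 4, 3))
  vox <- as.matrix(expand.grid(1:5, 1:4, 1:3))[1:33 %% 2 == 1, ]
  colnames(vox) <- NULL
  manual <- rep(0, 30)
  for (r in seq_len(nrow(vox)))
    manual <- manual + b$data[vox[r, 1], vox[r, 2], vox[r, 3], ]
  expect_equal(extract_seed_timeseries(b, vox), manual / nrow(vox),
               tolerance = 1e-12)
  expect_error(extract_seed_timeseries(b, vox[0, , drop = FALSE]), "empty")
})

test_that("dFC variance map equals the naive triple-loop reference", {
  d <- c(5, 1, 1)
  nt <- 60
  b <- toy_bold(d, nt, seed = 31)
  seed_series <- rnorm(nt) + 0.5 * b$data[3, 1, 1, ]
  mask <- toy_mask(d)
  w <- window_spec(15, 3)
  got <- dfc_variance_map(b, seed_series, w, mask)
  ref <- oracle_dfc_map(b, seed_series, w, mask)
  expect_equal(got$data, ref, tolerance = 1e-10)
  expect_equal(got$n_windows, count_windows(nt, w))
  # rectangular taper path too
  wr <- window_spec(15, 3, taper = "rectangular")
  expect_equal(dfc_variance_map(b, seed_series, wr, mask)$data,
               oracle_dfc_map(b, seed_series, wr, mask), tolerance = 1e-10)
})

test_that("a voxel identical to the seed has zero dFC variance", {
  d <- c(3, 1, 1)
  nt <- 80
  set.seed(6)
  s <- rnorm(nt)
  arr <- array(rnorm(prod(d) * nt), c(d, nt))
  arr[2, 1, 1, ] <- s
  b <- bold4d(arr, toy_mask(d)$affine, 2)
  m <- dfc_variance_map(b, s, window_spec(20, 2), toy_mask(d))
  expect_equal(m$data[2, 1, 1], 0, tolerance = 1e-12)
  expect_gt(m$data[1, 1, 1], 0)
})

test_that("dFC variance is invariant to positive affine rescaling", {
  d <- c(4, 2, 1)
  nt <- 70
  b <- toy_bold(d, nt, seed = 13)
  s <- rnorm(nt)
  mask <- toy_mask(d)
  w <- window_spec(20, 5)
  base <- dfc_variance_map(b, s, w, mask)
  b2 <- bold4d(3.7 * b$data + 11, b$affine, b$tr_s)
  scaled <- dfc_variance_map(b2, -0 + 2.2 * s + 4, w, mask)
  expect_equal(scaled$data, base$data, tolerance = 1e-10)
})

test_that("longer windows damp sampling variability of stationary coupling", {
  # i.i.d.-coupled stationary signals: dFC variance reflects only sampling
  # noise, which shrinks as windows lengthen
  d <- c(6, 6, 1)
  nt <- 150
  set.seed(40)
  s <- rnorm(nt)
  arr <- array(0.6 * rep(s, each = prod(d)) + rnorm(prod(d) * nt), c(d, nt))
  b <- bold4d(arr, toy_mask(d)$affine, 2)
  mask <- toy_mask(d)
  v <- vapply(c(25, 50, 75), function(L)
    mean(dfc_variance_map(b, s, window_spec(L, 1), mask)$data), 0)
  expect_true(all(diff(v) < 0))
})

test_that("subject-wise standardization z-scores the map across voxels", {
  d <- c(6, 6, 1)
  b <- toy_bold(d, 60, seed = 19)
  s <- rnorm(60)
  mask <- toy_mask(d)
  raw <- dfc_variance_map(b, s, window_spec(20, 4), mask)
  std <- dfc_variance_map(b, s, window_spec(20, 4), mask,
                          standardize = TRUE)
  v <- std$data[mask$data]
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(sd(v), 1, tolerance = 1e-12)
  expect_equal(v, as.numeric(scale(raw$data[mask$data])),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("NaN appears only outside the mask", {
  d <- c(6, 6, 6)
  b <- toy_bold(d, 40, seed = 2)
  mask <- toy_mask(d)
  mask$data[1:2, , ] <- FALSE
  m <- dfc_variance_map(b, rnorm(40), window_spec(10, 2), mask)
  expect_true(all(is.na(m$data[!mask$data])))
  expect_false(anyNA(m$data[mask$data]))
  expect_true(all(m$data[mask$data] >= 0))
})
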