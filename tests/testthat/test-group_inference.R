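arr1 <- function(v) array(v, c(1, 1, 1))

test_that("pooled t map matches hand and t.test values", {
  mask <- toy_mask(c(1, 1, 1))
  g1 <- lapply(c(1, 2, 3), arr1)
  g2 <- lapply(c(4, 5, 6), arr1)
  tm <- two_sample_t_map(g1, g2, mask)
  expect_equal(tm$t[1, 1, 1], -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tm$t[1, 1, 1], -3.674, tolerance = 1e-3)
  expect_equal(tm$df, 4L)
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(tm$t[1, 1, 1], unname(tt$statistic), tolerance = 1e-12)
})

test_that("identical group means give a zero t map", {
  mask <- toy_mask(c(2, 2, 2))
  set.seed(3)
  a <- array(rnorm(8), c(2, 2, 2))
  b <- array(rnorm(8), c(2, 2, 2))
  tm <- two_sample_t_map(list(a, b), list(a, b), mask)
  expect_lt(max(abs(tm$t)), 1e-12)
})

test_that("zero pooled variance becomes NA with a message", {
  mask <- toy_mask(c(1, 1, 1))
  expect_message(
    tm <- two_sample_t_map(lapply(c(1, 1), arr1), lapply(c(1, 1), arr1),
                           mask),
    "zero pooled variance")
  expect_true(is.na(tm$t[1, 1, 1]))
})

test_that("summary-statistic t reproduces the study's Table-style values", {
  t_co <- two_sample_t_from_summary(15.90, 8.98, 31, 1.52, 0.75, 27)
  expect_lt(abs(t_co - 8.293) / 8.293, 0.02)
  t_age <- two_sample_t_from_summary(30.32, 6.48, 31, 29.37, 5.56, 27)
  expect_lt(abs(t_age - 0.596) / 0.596, 0.02)
  expect_equal(two_sample_t_from_summary(5, 1, 10, 5, 2, 12), 0)
  expect_error(two_sample_t_from_summary(1, 0, 5, 2, 0, 5), "undefined")
})

test_that("map t equals summary t applied voxelwise", {
  mask <- toy_mask(c(3, 3, 2))
  set.seed(14)
  g1 <- replicate(5, array(rnorm(18), c(3, 3, 2)), simplify = FALSE)
  g2 <- replicate(5, array(rnorm(18, 0.3), c(3, 3, 2)), simplify = FALSE)
  tm <- two_sample_t_map(g1, g2, mask)
  M1 <- sapply(g1, as.numeric)
  M2 <- sapply(g2, as.numeric)
  manual <- vapply(seq_len(18), function(v)
    two_sample_t_from_summary(mean(M1[v, ]), sd(M1[v, ]), 5,
                              mean(M2[v, ]), sd(M2[v, ]), 5), 0)
  expect_equal(as.numeric(tm$t), manual, tolerance = 1e-10)
  # and the pooled-t oracle (voxel (2,2,1) has linear index 5 in 3x3x2)
  expect_equal(tm$t[2, 2, 1], oracle_pooled_t(M1[5, ], M2[5, ]),
               tolerance = 1e-10)
})

test_that("smoothness estimation recovers a known kernel", {
  cfg <- sim_config(n_group1 = 8, n_group2 = 8)
  mask <- sim_brain_mask(cfg)
  d <- dim(mask$data)
  set.seed(77)
  smoothed <- replicate(10, smooth_volume(array(rnorm(prod(d)), d), 6,
                                          c(3, 3, 3)), simplify = FALSE)
  rough <- replicate(10, array(rnorm(prod(d)), d), simplify = FALSE)
  res_s <- sapply(smoothed, function(a) a[mask$data])
  res_s <- res_s - rowMeans(res_s)
  sm <- estimate_smoothness(res_s, mask)
  expect_true(all(abs(sm$fwhm_mm - 6) / 6 < 0.15))
  res_r <- sapply(rough, function(a) a[mask$data])
  res_r <- res_r - rowMeans(res_r)
  sm_r <- estimate_smoothness(res_r, mask)
  expect_true(all(abs(sm_r$fwhm_mm - 3) / 3 < 0.2))
  expect_gt(sm_r$resel_count, sm$resel_count)
  expect_error(estimate_smoothness(res_s * 0, mask), "zero")
})

test_that("cluster labelling respects the connectivity scheme", {
  a <- array(FALSE, c(4, 4, 4))
  a[1, 1, 1] <- TRUE
  a[2, 2, 1] <- TRUE  # edge-diagonal neighbor
  a[2, 1, 1] <- FALSE
  lab6 <- dfcvar:::label_clusters(a, 6L)
  expect_length(lab6$voxels, 2L)
  lab18 <- dfcvar:::label_clusters(a, 18L)
  expect_length(lab18$voxels, 1L)
  a[2, 2, 2] <- TRUE  # corner-diagonal from (1,1,1)
  lab18b <- dfcvar:::label_clusters(a, 18L)
  expect_length(lab18b$voxels, 1L)  # chained via (2,2,1)
  b <- array(FALSE, c(3, 3, 3))
  b[1, 1, 1] <- TRUE
  b[2, 2, 2] <- TRUE
  expect_length(dfcvar:::label_clusters(b, 18L)$voxels, 2L)
  expect_length(dfcvar:::label_clusters(b, 26L)$voxels, 1L)
  # face-connected run is one cluster
  cc <- array(FALSE, c(5, 1, 1))
  cc[2:4, 1, 1] <- TRUE
  expect_equal(unname(lengths(dfcvar:::label_clusters(cc, 6L)$voxels)), 3L)
})

test_that("GRF correction returns an empty table below threshold", {
  mask <- toy_mask(c(8, 8, 8))
  tmap <- list(t = array(0.5, c(8, 8, 8)), df = 40L)
  sm <- smoothness_from_fwhm(6, mask)
  ct <- grf_cluster_correction(tmap, mask, sm)
  expect_equal(nrow(ct$table), 0L)
})

test_that("GRF corrected p is monotone non-increasing in cluster extent", {
  mask <- toy_mask(c(20, 20, 20))
  sm <- smoothness_from_fwhm(6, mask)
  df <- 56L
  u <- qt(1 - 0.005 / 2, df)
  em <- 2 * sm$resel_count * dfcvar:::ec_density_t3(u, df)
  en <- 2 * sum(mask$data) * pt(u, df, lower.tail = FALSE)
  beta <- (gamma(2.5) / (en / em))^(2 / 3)
  p <- 1 - exp(-em * exp(-beta * (1:200)^(2 / 3)))
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p > 0 & p <= 1))
})

test_that("an injected blob survives with the right sign convention", {
  # smokers lower than controls in a block -> negative peak t
  cfg <- sim_config(n_group1 = 6, n_group2 = 6)
  mask <- sim_brain_mask(cfg)
  d <- dim(mask$data)
  blob <- array(0, d)
  blob[10:14, 12:16, 10:14] <- 1
  blob <- smooth_volume(blob, 6, c(3, 3, 3))
  set.seed(20)
  g1 <- replicate(6, smooth_volume(array(rnorm(prod(d)), d), 6, c(3, 3, 3)) -
                    3 * blob, simplify = FALSE)
  g2 <- replicate(6, smooth_volume(array(rnorm(prod(d)), d), 6, c(3, 3, 3)),
                  simplify = FALSE)
  tm <- two_sample_t_map(g1, g2, mask)
  sm <- estimate_smoothness(tm$residuals, mask)
  ct <- grf_cluster_correction(tm, mask, sm)
  expect_gte(nrow(ct$table), 1L)
  expect_equal(ct$table$sign[1], -1)
  expect_lt(ct$table$peak_t[1], 0)
  pk_vox <- drop(world_to_voxel(as.numeric(ct$table[1, c("peak_x", "peak_y",
                                                         "peak_z")]),
                                mask$affine))
  expect_true(all(pk_vox >= c(8, 10, 8) & pk_vox <= c(16, 18, 16)))
  # table serializes
  path <- withr::local_tempfile(fileext = ".csv")
  write_cluster_table(ct, path)
  got <- read.csv(path)
  expect_equal(got$size_voxels, ct$table$size_voxels)
})

test_that("Pearson correlations with BH-FDR behave as the step-up rule", {
  set.seed(8)
  f <- data.frame(c1 = rnorm(20))
  b <- data.frame(y = 2 * f$c1 + 1)
  out <- pearson_with_fdr(f, b)
  expect_equal(out$r, 1, tolerance = 1e-12)

  # the adjusted significance matches the hand-applied step-up rule
  p_hand <- c(0.001, 0.02, 0.03, 0.2)
  adj <- p.adjust(p_hand, "BH")
  expect_equal(adj <= 0.05, c(TRUE, TRUE, TRUE, FALSE))

  # oracle equivalence over random p vectors, m <= 10
  for (i in 1:25) {
    m <- sample(1:10, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH") <= 0.05, oracle_bh_reject(p, 0.05))
  }
})

test_that("constant features are skipped and short inputs rejected", {
  f <- data.frame(c1 = rep(1, 10), c2 = rnorm(10))
  b <- data.frame(y = rnorm(10))
  expect_message(out <- pearson_with_fdr(f, b), "constant")
  expect_equal(nrow(out), 1L)
  expect_error(pearson_with_fdr(data.frame(x = 1:2), data.frame(y = 1:2)),
               "fewer than 3")
})
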