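# Independent brute-force reference implementations used to check the
# package's vectorized paths. Deliberately naive: plain loops and two-pass
# moment formulas.

# two-pass weighted Pearson correlation
oracle_weighted_cor <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  num <- 0
  vx <- 0
  vy <- 0
  for (i in seq_along(x)) {
    num <- num + w[i] * (x[i] - mx) * (y[i] - my)
    vx <- vx + w[i] * (x[i] - mx)^2
    vy <- vy + w[i] * (y[i] - my)^2
  }
  num / sqrt(vx * vy)
}

# triple-loop dFC variance map: voxels x windows, naive moments throughout
oracle_dfc_map <- function(bold, seed_series, window, mask) {
  d <- dim(bold$data)
  L <- window$length_tr
  K <- (d[4] - L) %/% window$step_tr + 1
  w <- if (window$taper == "hamming")
    0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1)) else rep(1, L)
  out <- array(NA_real_, d[1:3])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k3 in seq_len(d[3])) {
    if (!mask$data[i, j, k3]) next
    v <- bold$data[i, j, k3, ]
    z <- numeric(K)
    for (k in seq_len(K)) {
      s0 <- (k - 1) * window$step_tr
      r <- oracle_weighted_cor(seed_series[s0 + seq_len(L)],
                               v[s0 + seq_len(L)], w)
      r <- max(min(r, 1 - 1e-7), -(1 - 1e-7))
      z[k] <- 0.5 * log((1 + r) / (1 - r))
    }
    out[i, j, k3] <- stats::sd(z)
  }
  out
}

# pooled two-sample t, textbook formula
oracle_pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# Benjamini-Hochberg step-up by exhaustive search: among all 2^m rejection
# sets that respect the step-up constraint (reject the k smallest p-values
# with p_(k) <= k q / m), return the maximal one.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  best_k <- 0L
  for (k in seq_len(m)) if (ps[k] <= k * q / m) best_k <- k
  rej <- logical(m)
  if (best_k > 0L) rej[ord[seq_len(best_k)]] <- TRUE
  rej
}

# small all-true-mask grid for toy tests
toy_mask <- function(d, voxel_mm = 3) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -(d + 1) / 2 * voxel_mm
  brain_mask(array(TRUE, d), aff)
}

toy_bold <- function(d, nt, tr_s = 2, seed = 1) {
  set.seed(seed)
  bold4d(array(rnorm(prod(d) * nt), c(d, nt)), toy_mask(d)$affine, tr_s)
}

# tiny simulation config for fast structural tests; overrides win
tiny_config <- function(...) {
  args <- list(n_group1 = 2L, n_group2 = 2L, grid_shape = c(12L, 12L, 12L),
               seed_specs = list(seed_spec("sim seed", c(-3, 3, 0), 4)),
               effect_regions = list(list(seed = "sim seed",
                                          center_mni = c(6, -6, 3),
                                          radius_mm = 4, a = 1,
                                          b_group1 = 0.8, b_group2 = 0.2)))
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# phenotype table fixture matching the study schema
cohort_table_fixture <- function(n_smokers, n_controls, seed = 99) {
  set.seed(seed)
  n <- n_smokers + n_controls
  data.frame(
    id = sprintf("sub-%02d", seq_len(n)),
    group = rep(c("smoker", "control"), c(n_smokers, n_controls)),
    age = round(runif(n, 20, 44), 1),
    education = round(runif(n, 9, 18), 1),
    co_ppm = round(c(runif(n_smokers, 6, 30), runif(n_controls, 0, 3)), 1),
    smoking_years = c(round(runif(n_smokers, 1, 20), 1),
                      rep(NA_real_, n_controls)),
    cigs_per_day = c(round(runif(n_smokers, 4, 30)),
                     rep(NA_real_, n_controls)),
    ftcd = c(round(runif(n_smokers, 1, 9), 1), rep(NA_real_, n_controls)),
    stringsAsFactors = FALSE)
}
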