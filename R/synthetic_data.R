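# Synthetic two-group BOLD cohort with known injected group differences in
# dynamic seed-target coupling, plus motion/WM/CSF confounds and a phenotype
# table matched to the study's covariate schema.

#' Simulation configuration
#'
#' Defines a two-group resting-state cohort on a desk-scale 3 mm grid.
#' Group 1 plays the smokers (31 subjects), group 2 the controls (27); 210
#' volumes at TR 2 s. Each seed drives a band-limited (0.01-0.08 Hz) signal;
#' inside an effect region the seed-coupling gain fluctuates slowly as
#' `a + b_g m(t)` with `m(t)` a random-phase unit-variance sinusoid, so the
#' group difference in the modulation amplitude `b` maps directly onto a
#' group difference in dFC variance.
#'
#' @param n_group1,n_group2 subject counts (>= 2 each; defaults 31 and 27).
#' @param grid_shape 3D grid dimensions (default `c(24, 28, 24)`).
#' @param voxel_mm isotropic voxel size in mm (default 3).
#' @param n_timepoints volumes per subject (default 210).
#' @param tr_s repetition time in seconds (default 2).
#' @param seed_specs list of [seed_spec]; the default single seed sits at
#'   (-15, 12, -6) mm, on a voxel center of the desk-scale grid.
#' @param effect_regions list of effect definitions: each a list with
#'   `seed` (seed name), `center_mni`, `radius_mm`, `a` (mean coupling),
#'   `b_group1`, `b_group2` (per-group modulation amplitudes).
#' @param noise_sd white-noise SD added to seed/effect voxels (default 1).
#' @param modulation_period_s period of the coupling modulator (default 160
#'   s: slower than the 100 s analysis window so windows resolve it, while
#'   still completing ~2.5 cycles in a 400 s analyzed run; must exceed
#'   `2 * tr_s`).
#' @param confound_amp scale of the injected motion/WM/CSF signal leakage
#'   (default 0.5).
#' @param b_sd subject-level SD of the modulation amplitude around the group
#'   mean (default 0; used to induce brain-behavior correlation).
#' @param behavior_rho correlation between a group-1 subject's modulation
#'   amplitude and the smoking-years covariate (default 0).
#' @param rng_seed integer; the whole dataset is a pure function of the
#'   config including this seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_group1 = 31L, n_group2 = 27L,
                       grid_shape = c(24L, 28L, 24L), voxel_mm = 3,
                       n_timepoints = 210L, tr_s = 2,
                       seed_specs = list(seed_spec("sim seed",
                                                   c(-15, 12, -6), 6)),
                       effect_regions = list(list(seed = "sim seed",
                                                  center_mni = c(15, -21, 12),
                                                  radius_mm = 7.5,
                                                  a = 1,
                                                  b_group1 = 0.8,
                                                  b_group2 = 0.2)),
                       noise_sd = 1, modulation_period_s = 160,
                       confound_amp = 0.5, b_sd = 0, behavior_rho = 0,
                       rng_seed = 42L) {
  stopifnot(n_group1 >= 2L, n_group2 >= 2L, length(grid_shape) == 3L,
            n_timepoints >= 2L, tr_s > 0, noise_sd >= 0,
            modulation_period_s > 2 * tr_s, confound_amp >= 0,
            b_sd >= 0, abs(behavior_rho) <= 1)
  for (er in effect_regions)
    stopifnot(er$b_group1 >= 0, er$b_group2 >= 0)
  nm <- vapply(seed_specs, function(s) s$name, "")
  if (anyDuplicated(nm)) stop("seed names must be unique")
  structure(list(n_group1 = as.integer(n_group1),
                 n_group2 = as.integer(n_group2),
                 grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 n_timepoints = as.integer(n_timepoints), tr_s = tr_s,
                 seed_specs = seed_specs, effect_regions = effect_regions,
                 noise_sd = noise_sd,
                 modulation_period_s = modulation_period_s,
                 confound_amp = confound_amp, b_sd = b_sd,
                 behavior_rho = behavior_rho,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Simulation grid geometry
#'
#' `sim_affine()` centers the grid on the origin (3 mm steps, RAS);
#' `sim_brain_mask()` returns the ellipsoidal "brain" inscribed in the grid.
#'
#' @param config a [sim_config].
#' @return 4x4 affine / [brain_mask].
#' @export
sim_affine <- function(config) {
  aff <- diag(c(rep(config$voxel_mm, 3), 1))
  aff[1:3, 4] <- -config$grid_shape / 2 * config$voxel_mm
  aff
}

#' @rdname sim_affine
#' @export
sim_brain_mask <- function(config) {
  d <- config$grid_shape
  ctr <- (d + 1) / 2
  semi <- d / 2 - 1
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  inside <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2 <= 1
  brain_mask(array(inside, d), sim_affine(config))
}

# band-limited unit-variance Gaussian process (ideal-filtered white noise)
bandlimited_series <- function(n, tr_s, low_hz = 0.01, high_hz = 0.08) {
  x <- stats::rnorm(n)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * tr_s)
  keep <- f >= low_hz & f <= high_hz & k != 0
  xf <- stats::fft(x)
  xf[!keep] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE)) / n
  y / stats::sd(y)
}

# 1/f-like noise: amplitude ~ f^(-1/2) above a low-frequency floor
one_over_f_noise <- function(n, n_series, tr_s) {
  W <- matrix(stats::rnorm(n * n_series), n, n_series)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * tr_s)
  g <- 1 / sqrt(pmax(f, 1 / (n * tr_s)))
  g[1] <- 0  # no DC
  Fy <- stats::mvfft(W) * g
  y <- Re(stats::mvfft(Fy, inverse = TRUE)) / n
  sc <- sqrt(colMeans(y^2))
  sweep(y, 2, pmax(sc, .Machine$double.eps), "/")
}

smooth_random_walk <- function(n, scale) {
  x <- cumsum(stats::rnorm(n, sd = 1))
  x <- x - mean(x)
  x / max(abs(x), .Machine$double.eps) * scale
}

ar1_series <- function(n, phi = 0.9) {
  x <- as.numeric(stats::filter(stats::rnorm(n), phi, "recursive"))
  (x - mean(x)) / stats::sd(x)
}

#' Simulate one subject's BOLD run
#'
#' Generative model: each seed sphere carries a band-limited (0.01-0.08 Hz)
#' unit-variance driver `s(t)` plus white noise; effect-region voxels follow
#' `(a + b m(t)) s(t)` plus white noise, with `m(t)` a random-phase sinusoid
#' of period `modulation_period_s` (zero mean, unit variance); all other
#' in-mask voxels carry independent 1/f-like noise. Every in-mask voxel
#' additionally receives `confound_amp`-scaled random combinations of 6
#' synthetic motion regressors and 2 nuisance (WM/CSF-like) series, which are
#' returned so preprocessing can regress exactly what was injected.
#'
#' @param config a [sim_config].
#' @param group 1 or 2.
#' @param rng_seed integer seed for this subject's randomness.
#' @param b optional per-subject modulation amplitude(s), one per effect
#'   region; defaults to the group's `b_group*` values.
#' @return List: `bold` ([bold4d]), `motion` (T x 6), `nuisance` (T x 2),
#'   `b` (realized amplitudes), `seed_voxels`, `effect_voxels` (linear
#'   indices per region), `mask`.
#' @export
simulate_subject_bold <- function(config, group, rng_seed, b = NULL) {
  stopifnot(inherits(config, "sim_config"), group %in% c(1L, 2L))
  set.seed(as.integer(rng_seed))
  d <- config$grid_shape
  nt <- config$n_timepoints
  mask <- sim_brain_mask(config)
  lin_mask <- which(mask$data)
  nv <- length(lin_mask)

  seed_vox <- lapply(config$seed_specs, build_sphere_mask, grid = mask)
  names(seed_vox) <- vapply(config$seed_specs, function(s) s$name, "")
  drivers <- lapply(seed_vox, function(v)
    bandlimited_series(nt, config$tr_s))

  if (is.null(b))
    b <- vapply(config$effect_regions, function(er)
      if (group == 1L) er$b_group1 else er$b_group2, 0)
  stopifnot(length(b) == length(config$effect_regions), all(b >= 0))

  # background: independent 1/f-like noise everywhere in the mask
  Y <- one_over_f_noise(nt, nv, config$tr_s)  # nt x nv
  col_of <- integer(prod(d))
  col_of[lin_mask] <- seq_len(nv)

  for (i in seq_along(seed_vox)) {
    cols <- col_of[attr(seed_vox[[i]], "linear")]
    Y[, cols] <- drivers[[i]] +
      config$noise_sd * matrix(stats::rnorm(nt * length(cols)), nt)
  }

  effect_lin <- vector("list", length(config$effect_regions))
  for (j in seq_along(config$effect_regions)) {
    er <- config$effect_regions[[j]]
    if (!er$seed %in% names(seed_vox))
      stop("effect region references unknown seed '", er$seed, "'")
    reg <- build_sphere_mask(seed_spec(paste0("effect_", j), er$center_mni,
                                       er$radius_mm), mask)
    lin <- attr(reg, "linear")
    if (any(lin %in% attr(seed_vox[[er$seed]], "linear")))
      stop("effect region ", j, " overlaps its seed sphere")
    effect_lin[[j]] <- lin
    phase <- stats::runif(1, 0, 2 * pi)
    m <- sqrt(2) * sin(2 * pi * (seq_len(nt) - 1) * config$tr_s /
                         config$modulation_period_s + phase)
    gain <- er$a + b[j] * m
    cols <- col_of[lin]
    Y[, cols] <- gain * drivers[[er$seed]] +
      config$noise_sd * matrix(stats::rnorm(nt * length(cols)), nt)
  }

  # injected confounds: slow motion drifts + AR(1) tissue signals
  motion <- cbind(
    sapply(1:3, function(i) smooth_random_walk(nt, 0.3)),     # mm
    sapply(1:3, function(i) smooth_random_walk(nt, 0.3)))     # degrees
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  nuis <- cbind(wm = ar1_series(nt), csf = ar1_series(nt))
  if (config$confound_amp > 0) {
    C <- cbind(sweep(motion, 2, apply(abs(motion), 2, max), "/"), nuis)
    loadings <- matrix(stats::rnorm(nv * ncol(C)), ncol(C), nv)
    Y <- Y + config$confound_amp * (C %*% loadings)
  }

  arr <- array(0, c(d, nt))
  flat <- matrix(arr, prod(d), nt)
  flat[lin_mask, ] <- t(Y)
  arr <- array(flat, c(d, nt))
  list(bold = bold4d(arr, sim_affine(config), config$tr_s),
       motion = motion, nuisance = nuis, b = b,
       seed_voxels = seed_vox, effect_voxels = effect_lin, mask = mask)
}

# per-subject seeds, covariates and amplitudes; pure function of the config
cohort_plan <- function(config) {
  set.seed(config$rng_seed)
  n1 <- config$n_group1
  n2 <- config$n_group2
  n <- n1 + n2
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n)
  group <- rep(c(1L, 2L), c(n1, n2))
  ids <- sprintf("sub-%02d", seq_len(n))

  rtrunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
    x <- stats::rnorm(n, mean, sd)
    for (it in 1:100) {
      bad <- x < lo | x > hi
      if (!any(bad)) break
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    pmin(pmax(x, lo), hi)
  }
  # covariates drawn from Gaussians matched to the study's group summaries
  age <- c(rtrunc(n1, 30.32, 6.48, 18, 45), rtrunc(n2, 29.37, 5.56, 18, 45))
  edu <- c(rtrunc(n1, 12.65, 2.26, 6, 22), rtrunc(n2, 13.70, 2.60, 6, 22))
  co  <- c(rtrunc(n1, 15.90, 8.98, 6, Inf), rtrunc(n2, 1.52, 0.75, 0, 3))

  zb <- stats::rnorm(n1)  # latent per-smoker amplitude deviation
  rho <- config$behavior_rho
  zy <- rho * zb + sqrt(1 - rho^2) * stats::rnorm(n1)
  smoking_years <- pmax(1, 8.87 + 6.63 * zy)
  cigs <- rtrunc(n1, 12.26, 8.19, 4, Inf)
  ftcd <- rtrunc(n1, 5.74, 1.36, 0, 10)

  b <- lapply(seq_len(n), function(i) {
    base <- vapply(config$effect_regions, function(er)
      if (group[i] == 1L) er$b_group1 else er$b_group2, 0)
    if (group[i] == 1L && config$b_sd > 0)
      base <- pmax(0, base + config$b_sd * zb[i])
    base
  })

  tab <- data.frame(
    id = ids, group = c("smoker", "control")[group],
    age = round(age, 1), education = round(edu, 1), co_ppm = round(co, 1),
    smoking_years = c(round(smoking_years, 1), rep(NA_real_, n2)),
    cigs_per_day = c(round(cigs, 0), rep(NA_real_, n2)),
    ftcd = c(round(ftcd, 1), rep(NA_real_, n2)),
    stringsAsFactors = FALSE)
  list(table = tab, group = group, subj_seeds = subj_seeds, b = b)
}

#' Generate an on-disk synthetic cohort
#'
#' Writes one 4D NIfTI per subject plus its motion (6-column TSV) and
#' nuisance (2-column TSV) series, a `participants.tsv` phenotype table and
#' a `ground_truth.json` sidecar. The dataset is a pure function of the
#' config (byte-identical given the same `rng_seed`).
#'
#' @param config a [sim_config].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list: `dir`, `table` (phenotype data.frame with file
#'   path columns), and `ground_truth` (effect-region voxels per seed,
#'   per-group amplitudes, per-subject realized amplitudes and rng seeds).
#' @export
generate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plan <- cohort_plan(config)
  tab <- plan$table
  n <- nrow(tab)
  tab$bold_path <- file.path(dir, paste0(tab$id, "_bold.nii.gz"))
  tab$motion_path <- file.path(dir, paste0(tab$id, "_motion.tsv"))
  tab$nuisance_path <- file.path(dir, paste0(tab$id, "_nuisance.tsv"))

  gt_effects <- NULL
  for (i in seq_len(n)) {
    sub <- simulate_subject_bold(config, plan$group[i],
                                 plan$subj_seeds[i], b = plan$b[[i]])
    write_bold(sub$bold, tab$bold_path[i], datatype = "float")
    write_series_tsv(sub$motion, tab$motion_path[i])
    write_series_tsv(sub$nuisance, tab$nuisance_path[i])
    if (is.null(gt_effects)) gt_effects <- sub$effect_voxels
  }
  # paths are stored relative to the dataset directory so the dataset is
  # byte-identical wherever it is generated
  rel <- tab
  for (cl in c("bold_path", "motion_path", "nuisance_path"))
    rel[[cl]] <- basename(rel[[cl]])
  write_subject_table(rel, file.path(dir, "participants.tsv"))

  gt <- list(
    grid_shape = config$grid_shape,
    effect_regions = lapply(seq_along(config$effect_regions), function(j) {
      er <- config$effect_regions[[j]]
      list(seed = er$seed, center_mni = er$center_mni,
           radius_mm = er$radius_mm, a = er$a,
           b_group1 = er$b_group1, b_group2 = er$b_group2,
           voxels_linear = gt_effects[[j]])
    }),
    subjects = list(id = tab$id, group = tab$group,
                    rng_seed = plan$subj_seeds,
                    b = do.call(rbind, plan$b)))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir, table = tab, ground_truth = gt))
}
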