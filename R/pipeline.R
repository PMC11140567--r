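# Study-level pipeline: stream a synthetic cohort through preprocessing and
# dFC mapping, run the group analysis, and calibration utilities.

#' Simulate a cohort and compute per-subject dFC variance maps
#'
#' Streams subjects one at a time (simulate -> preprocess -> seed series ->
#' dFC variance map) so only the 3D maps are kept in memory. Preprocessing
#' regresses exactly the injected motion and tissue confounds.
#'
#' @param config a [sim_config].
#' @param window a [window_spec] (default 50 TRs, step 1, Hamming).
#' @param n_discard leading volumes to drop (default 10).
#' @param fwhm_mm smoothing FWHM in mm (default 6).
#' @param low_hz,high_hz bandpass edges (defaults 0.01, 0.08 Hz).
#' @param verbose print a line per subject.
#' @return List of class `cohort_dfc`: `maps_by_seed` (seed name -> list of
#'   [dfc_variance_map] results, subject order matching `table`), `table`
#'   (phenotype data.frame), `mask`, `ground_truth` (effect voxel indices,
#'   per-subject amplitudes), `config`, `window`.
#' @export
run_cohort_dfc <- function(config, window = window_spec(),
                           n_discard = 10L, fwhm_mm = 6,
                           low_hz = 0.01, high_hz = 0.08,
                           verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  plan <- cohort_plan(config)
  n <- nrow(plan$table)
  mask <- sim_brain_mask(config)
  seed_names <- vapply(config$seed_specs, function(s) s$name, "")
  maps_by_seed <- stats::setNames(
    replicate(length(seed_names), vector("list", n), simplify = FALSE),
    seed_names)
  gt_effects <- NULL
  for (i in seq_len(n)) {
    sub <- simulate_subject_bold(config, plan$group[i],
                                 plan$subj_seeds[i], b = plan$b[[i]])
    pre <- preprocess_bold(sub$bold,
                           confound_set(sub$motion, sub$nuisance[, "wm"],
                                        sub$nuisance[, "csf"]),
                           n_discard = n_discard, low_hz = low_hz,
                           high_hz = high_hz, fwhm_mm = fwhm_mm)
    for (sn in seed_names) {
      series <- extract_seed_timeseries(pre, sub$seed_voxels[[sn]])
      maps_by_seed[[sn]][[i]] <-
        dfc_variance_map(pre, series, window, mask,
                         seed_name = sn, subject_id = plan$table$id[i])
    }
    if (is.null(gt_effects)) gt_effects <- sub$effect_voxels
    if (verbose)
      message(sprintf("  %s (%s) done", plan$table$id[i],
                      plan$table$group[i]))
  }
  structure(list(maps_by_seed = maps_by_seed, table = plan$table,
                 mask = mask,
                 ground_truth = list(effect_voxels = gt_effects,
                                     b = do.call(rbind, plan$b),
                                     group = plan$group),
                 config = config, window = window),
            class = "cohort_dfc")
}

#' Group inference on a cohort's dFC maps
#'
#' Two-sample t map (smokers minus controls), residual smoothness estimate,
#' and GRF cluster-level correction, for one seed's maps.
#'
#' @param cohort a `cohort_dfc` from [run_cohort_dfc].
#' @param seed_name which seed's maps to analyze (default: first).
#' @param voxel_p,cluster_p GRF thresholds (defaults 0.005 and 0.05).
#' @param ... passed to [grf_cluster_correction].
#' @return List: `tmap`, `smoothness`, `clusters` (a `cluster_table`),
#'   `seed_name`.
#' @export
run_group_inference <- function(cohort, seed_name = NULL,
                                voxel_p = 0.005, cluster_p = 0.05, ...) {
  stopifnot(inherits(cohort, "cohort_dfc"))
  if (is.null(seed_name)) seed_name <- names(cohort$maps_by_seed)[1]
  maps <- cohort$maps_by_seed[[seed_name]]
  if (is.null(maps)) stop("no maps for seed '", seed_name, "'")
  g1 <- cohort$table$group == "smoker"
  tmap <- two_sample_t_map(maps[g1], maps[!g1], cohort$mask)
  sm <- estimate_smoothness(tmap$residuals, cohort$mask, df = tmap$df)
  ct <- grf_cluster_correction(tmap, cohort$mask, sm,
                               voxel_p = voxel_p, cluster_p = cluster_p, ...)
  list(tmap = tmap, smoothness = sm, clusters = ct, seed_name = seed_name)
}

#' Overlap between surviving clusters and the ground-truth effect region
#'
#' @param clusters a `cluster_table`.
#' @param truth_voxels linear voxel indices of the injected effect region.
#' @return List: `recall` (fraction of truth voxels inside surviving
#'   clusters), `n_outside_clusters` (surviving clusters disjoint from the
#'   truth region), `size_ratio` (total surviving extent / truth extent).
#' @export
cluster_recovery <- function(clusters, truth_voxels) {
  vox <- unlist(clusters$clusters)
  disjoint <- vapply(clusters$clusters,
                     function(v) !any(v %in% truth_voxels), TRUE)
  list(recall = mean(truth_voxels %in% vox),
       n_outside_clusters = sum(disjoint),
       size_ratio = length(vox) / length(truth_voxels))
}

#' Monte-Carlo FWER calibration of the GRF cluster correction
#'
#' Simulates null two-group studies: per subject, white noise on the mask
#' grid smoothed to a known FWHM; pooled t map; GRF correction with the
#' known smoothness. Returns the fraction of replicates with at least one
#' surviving cluster, the family-wise error rate the procedure targets at
#' `cluster_p`.
#'
#' @param n_reps number of replicate studies (default 500).
#' @param n1,n2 subjects per group (defaults 10 each).
#' @param mask a [brain_mask] (default: desk-scale ellipsoid).
#' @param fwhm_mm smoothing kernel = known field FWHM (default 6).
#' @param voxel_p,cluster_p GRF thresholds.
#' @param rng_seed integer seed.
#' @return List: `fwer`, `n_reps`, `n_survivors` per replicate.
#' @export
grf_fwer_calibration <- function(n_reps = 500L, n1 = 10L, n2 = 10L,
                                 mask = sim_brain_mask(sim_config()),
                                 fwhm_mm = 6, voxel_p = 0.005,
                                 cluster_p = 0.05, rng_seed = 1L) {
  set.seed(as.integer(rng_seed))
  d <- dim(mask$data)
  vs <- voxel_sizes(mask$affine)
  sm <- smoothness_from_fwhm(fwhm_mm, mask)
  n_surv <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    g1 <- lapply(seq_len(n1), function(i)
      smooth_volume(array(stats::rnorm(prod(d)), d), fwhm_mm, vs))
    g2 <- lapply(seq_len(n2), function(i)
      smooth_volume(array(stats::rnorm(prod(d)), d), fwhm_mm, vs))
    tm <- suppressMessages(two_sample_t_map(g1, g2, mask))
    ct <- grf_cluster_correction(tm, mask, sm, voxel_p = voxel_p,
                                 cluster_p = cluster_p)
    n_surv[r] <- nrow(ct$table)
  }
  list(fwer = mean(n_surv > 0), n_reps = n_reps, n_survivors = n_surv)
}
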