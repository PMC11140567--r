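# Voxelwise two-sample inference with Gaussian-random-field cluster-level
# correction, and brain-behavior Pearson correlation with BH-FDR.

maps_to_matrix <- function(maps, lin) {
  out <- vapply(maps, function(m) {
    a <- if (inherits(m, "dfc_map")) m$data else m
    a[lin]
  }, numeric(length(lin)))
  matrix(out, nrow = length(lin))
}

#' Voxelwise pooled two-sample t map
#'
#' Per in-mask voxel, the pooled-variance two-sample t statistic
#' (group1 - group2, df = n1 + n2 - 2). Per-subject residual maps (map minus
#' its group mean map) are returned for smoothness estimation.
#'
#' @param maps_g1,maps_g2 lists of `dfc_map` objects or 3D arrays, all on the
#'   mask's grid.
#' @param mask a [brain_mask].
#' @return List of class `t_map`: `t` (3D array, `NA` outside mask and where
#'   pooled variance is zero), `df`, `residuals` (in-mask voxels x subjects),
#'   `n1`, `n2`, `mask`.
#' @export
two_sample_t_map <- function(maps_g1, maps_g2, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  n1 <- length(maps_g1)
  n2 <- length(maps_g2)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 subjects per group")
  for (m in c(maps_g1, maps_g2))
    if (inherits(m, "dfc_map"))
      check_same_grid(dim(m$data), m$affine, dim(mask$data), mask$affine,
                      "map and mask")
  lin <- which(mask$data)
  M1 <- maps_to_matrix(maps_g1, lin)
  M2 <- maps_to_matrix(maps_g2, lin)
  m1 <- rowMeans(M1)
  m2 <- rowMeans(M2)
  v1 <- rowSums((M1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((M2 - m2)^2) / (n2 - 1)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  zero <- sp2 <= 0
  if (any(zero, na.rm = TRUE)) {
    tval[zero] <- NA_real_
    message(sum(zero, na.rm = TRUE),
            " in-mask voxel(s) with zero pooled variance; t set to NA")
  }
  tarr <- array(NA_real_, dim(mask$data))
  tarr[lin] <- tval
  structure(list(t = tarr, df = df,
                 residuals = cbind(M1 - m1, M2 - m2),
                 n1 = n1, n2 = n2, mask = mask),
            class = "t_map")
}

#' Pooled two-sample t from summary statistics
#'
#' @param mean1,sd1,n1 group 1 mean, SD, size.
#' @param mean2,sd2,n2 group 2 mean, SD, size.
#' @return The pooled-variance t statistic (df = n1 + n2 - 2).
#' @export
two_sample_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0 && mean1 != mean2)
    stop("both SDs zero with unequal means: t undefined")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Residual-field smoothness (FWHM) estimate
#'
#' Standardizes the residual maps voxelwise, then estimates the per-axis
#' smoothness from the variance of spatial first differences of the
#' standardized residual fields:
#' `FWHM_i = delta_i * sqrt(4 ln 2 / E[(du)^2])`. The resel count is the
#' in-mask volume divided by the product of the per-axis FWHMs.
#'
#' @param residuals in-mask voxels x subjects matrix (from
#'   [two_sample_t_map]), or a list of 3D residual arrays.
#' @param mask a [brain_mask].
#' @param df residual degrees of freedom (defaults to maps minus one; a
#'   two-group mean model has maps minus two). Voxelwise standardization
#'   fixes each voxel's residual sum of squares at `df`, so squared
#'   differences are rescaled by `M / df` to refer to a unit-variance field.
#' @return List of class `smoothness`: `fwhm_mm` (length 3), `resel_count`,
#'   `n_voxels`.
#' @export
estimate_smoothness <- function(residuals, mask, df = NULL) {
  stopifnot(inherits(mask, "brain_mask"))
  lin <- which(mask$data)
  if (is.list(residuals)) residuals <- maps_to_matrix(residuals, lin)
  if (ncol(residuals) < 3L) stop("need >= 3 residual maps")
  if (nrow(residuals) != length(lin))
    stop("residual rows do not match the mask")
  M <- ncol(residuals)
  if (is.null(df)) df <- M - 1L
  stopifnot(df >= 1)
  sd_vox <- sqrt(rowSums(residuals^2) / df)
  if (all(sd_vox == 0)) stop("all residuals are zero")
  U <- residuals / pmax(sd_vox, .Machine$double.eps)

  d <- dim(mask$data)
  vs <- voxel_sizes(mask$affine)
  fwhm <- numeric(3)
  for (ax in 1:3) {
    idx <- arrayInd(lin, d)
    nb <- idx
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    nb_lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
    ok <- ok & (mask$data[pmin(nb_lin, prod(d))] & ok)
    pos <- match(nb_lin[ok], lin)
    here <- which(ok)
    if (length(here) < 2L) stop("too few in-mask neighbor pairs on axis ", ax)
    dsq <- mean((U[pos, , drop = FALSE] - U[here, , drop = FALSE])^2) *
      M / df
    lambda <- dsq / vs[ax]^2
    fwhm[ax] <- sqrt(4 * log(2) / lambda)
  }
  fwhm <- pmax(fwhm, vs * 0.5)
  structure(list(fwhm_mm = fwhm,
                 resel_count = length(lin) * prod(vs) / prod(fwhm),
                 n_voxels = length(lin)),
            class = "smoothness")
}

#' Known-smoothness constructor
#'
#' Builds a `smoothness` object from a stated FWHM (e.g. for simulated
#' fields of known smoothness).
#'
#' @param fwhm_mm per-axis FWHM in mm (length 1 or 3).
#' @param mask a [brain_mask].
#' @return A `smoothness` object.
#' @export
smoothness_from_fwhm <- function(fwhm_mm, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  fwhm <- rep_len(as.numeric(fwhm_mm), 3)
  vs <- voxel_sizes(mask$affine)
  n <- sum(mask$data)
  structure(list(fwhm_mm = fwhm,
                 resel_count = n * prod(vs) / prod(fwhm),
                 n_voxels = n),
            class = "smoothness")
}

# 3D Euler-characteristic density of a t field at threshold u (per resel)
ec_density_t3 <- function(u, df) {
  (4 * log(2))^(3 / 2) / (2 * pi)^2 *
    (1 + u^2 / df)^(-(df - 1) / 2) * ((df - 1) / df * u^2 - 1)
}

# face-connected (or 18/26) components of a logical 3D array
label_clusters <- function(supra, connectivity = 6L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  d <- dim(supra)
  lin <- which(supra)
  if (length(lin) == 0L)
    return(list(labels = integer(0), voxels = list(), lin = integer(0)))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(offs))
  max_s <- switch(as.character(connectivity), "6" = 1L, "18" = 2L, "26" = 3L)
  offs <- offs[s >= 1L & s <= max_s, , drop = FALSE]
  # one direction per symmetric pair (first nonzero component positive)
  offs <- offs[apply(offs, 1, function(r) r[which(r != 0)[1]] > 0), ,
               drop = FALSE]
  idx <- arrayInd(lin, d)
  id_of <- integer(prod(d))
  id_of[lin] <- seq_along(lin)
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
      (nb[ok, 3] - 1L) * d[1] * d[2]
    tgt <- id_of[nb_lin]
    src <- which(ok)[tgt > 0L]
    edges <- rbind(edges, cbind(src, tgt[tgt > 0L]))
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  list(labels = comp,
       voxels = split(lin, comp),
       lin = lin)
}

#' GRF cluster-level correction of a t map
#'
#' Two-tailed cluster inference on a t field: the voxel threshold is the
#' upper `voxel_p / 2` t quantile (so both tails jointly spend `voxel_p`);
#' positive and negative suprathreshold voxels are clustered separately by
#' face connectivity. The cluster-extent null comes from random-field
#' theory for the two-sided `|t|` excursion set: expected cluster count
#' `E[m]` from the expected Euler characteristic, expected extent from the
#' expected suprathreshold volume over `E[m]`, extent tail
#' `P(N >= k) = exp(-beta k^(2/3))` with `beta` matched to the expected
#' extent, and corrected `p = 1 - exp(-E[m] P(N >= k))`.
#'
#' @param tmap a `t_map` from [two_sample_t_map] (or a list with `t` and
#'   `df`).
#' @param mask a [brain_mask].
#' @param smoothness a `smoothness` object.
#' @param voxel_p two-tailed voxel-level threshold (default 0.005).
#' @param cluster_p cluster-level significance threshold (default 0.05).
#' @param per_tail if `TRUE`, spend the full `voxel_p` in each tail instead
#'   of splitting it.
#' @param connectivity 6 (faces, default), 18 or 26.
#' @return An object of class `cluster_table`: `table` (data.frame with
#'   `sign`, `size_voxels`, `peak_x/y/z` mm, `peak_t`, `p_corrected`),
#'   `clusters` (list of linear voxel index vectors, same order), plus the
#'   threshold `u` and `E[m]` used.
#' @export
grf_cluster_correction <- function(tmap, mask, smoothness,
                                   voxel_p = 0.005, cluster_p = 0.05,
                                   per_tail = FALSE, connectivity = 6L) {
  stopifnot(inherits(mask, "brain_mask"),
            inherits(smoothness, "smoothness"),
            voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1)
  if (!all(is.finite(smoothness$fwhm_mm)) ||
      !is.finite(smoothness$resel_count))
    stop("non-finite smoothness estimate")
  df <- tmap$df
  tail_p <- if (per_tail) voxel_p else voxel_p / 2
  u <- stats::qt(1 - tail_p, df)

  em <- 2 * smoothness$resel_count * max(ec_density_t3(u, df), 1e-12)
  en <- 2 * sum(mask$data) * stats::pt(u, df, lower.tail = FALSE)
  nbar <- en / em
  beta <- (gamma(5 / 2) / nbar)^(2 / 3)

  tarr <- tmap$t
  tarr[!mask$data] <- NA
  rows <- list()
  clus <- list()
  for (sgn in c(1, -1)) {
    supra <- array(FALSE, dim(tarr))
    supra[which(sgn * tarr > u)] <- TRUE
    lab <- label_clusters(supra, connectivity)
    for (vox in lab$voxels) {
      k <- length(vox)
      p_ext <- exp(-beta * k^(2 / 3))
      p_corr <- 1 - exp(-em * p_ext)
      if (p_corr < cluster_p) {
        tv <- tarr[vox]
        pk <- vox[which.max(abs(tv))]
        pk_mm <- drop(voxel_to_world(arrayInd(pk, dim(tarr)), mask$affine))
        rows[[length(rows) + 1L]] <-
          data.frame(sign = sgn, size_voxels = k,
                     peak_x = pk_mm[1], peak_y = pk_mm[2], peak_z = pk_mm[3],
                     peak_t = tv[which.max(abs(tv))], p_corrected = p_corr)
        clus[[length(clus) + 1L]] <- vox
      }
    }
  }
  if (length(rows)) {
    tab <- do.call(rbind, rows)
    ord <- order(-abs(tab$peak_t))
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
    clus <- clus[ord]
  } else {
    tab <- data.frame(sign = integer(0), size_voxels = integer(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0), peak_t = numeric(0),
                      p_corrected = numeric(0))
  }
  structure(list(table = tab, clusters = clus, u = u, df = df,
                 expected_clusters = em, expected_extent = nbar,
                 voxel_p = voxel_p, cluster_p = cluster_p),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("<cluster_table> %d surviving cluster(s), |t| > %.3f (df %d)\n",
              nrow(x$table), x$u, x$df))
  if (nrow(x$table)) print(x$table, digits = 4)
  invisible(x)
}

#' Write a cluster table as CSV
#'
#' @param ct a `cluster_table`.
#' @param path output CSV path.
#' @export
write_cluster_table <- function(ct, path) {
  utils::write.csv(ct$table, path, row.names = FALSE)
  invisible(path)
}

#' Brain-behavior Pearson correlations with BH-FDR
#'
#' Pearson r and two-sided p for every (cluster feature, behavior) pair,
#' with Benjamini-Hochberg correction across all pairs in one family.
#' Constant features or behaviors are skipped with a message.
#'
#' @param features subjects x clusters numeric matrix or data.frame.
#' @param behaviors subjects x behaviors numeric matrix or data.frame
#'   (e.g. smoking_years, cigs_per_day, ftcd), same rows as `features`.
#' @param q FDR level (default 0.05).
#' @return data.frame with `cluster`, `behavior`, `n`, `r`, `p`, `p_fdr`,
#'   `significant`.
#' @export
pearson_with_fdr <- function(features, behaviors, q = 0.05) {
  features <- as.data.frame(features)
  behaviors <- as.data.frame(behaviors)
  if (nrow(features) != nrow(behaviors))
    stop("features and behaviors must cover the same subjects")
  rows <- list()
  for (fc in names(features)) for (bc in names(behaviors)) {
    x <- features[[fc]]
    y <- behaviors[[bc]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) stop("fewer than 3 paired observations for ",
                           fc, " x ", bc)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      message("skipping constant pair ", fc, " x ", bc)
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    rows[[length(rows) + 1L]] <-
      data.frame(cluster = fc, behavior = bc, n = sum(ok),
                 r = unname(ct$estimate), p = ct$p.value)
  }
  if (!length(rows)) stop("no testable (cluster, behavior) pairs")
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_fdr <= q
  rownames(out) <- NULL
  out
}
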