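# Domain types and I/O: 4D BOLD containers, brain masks, spherical seeds,
# subject tables, confound series.

#' 4D BOLD container
#'
#' Bundles a 4D intensity array with its voxel-to-world affine and repetition
#' time. This is the unit every preprocessing and connectivity operation
#' consumes and returns.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-world (mm) transform, RAS convention. Voxel
#'   indices are 1-based in R; the affine maps 0-based indices as stored in
#'   the NIfTI header, so conversion helpers subtract 1.
#' @param tr_s repetition time in seconds (> 0).
#' @return An object of class `bold4d`.
#' @export
bold4d <- function(data, affine, tr_s) {
  if (length(dim(data)) != 4L)
    stop("expected 4D data, got ", length(dim(data)), "D")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop("tr_s must be a single positive number")
  affine <- as_affine(affine)
  if (any(dim(data)[1:3] < 1L) || dim(data)[4] < 1L)
    stop("all dimensions must be >= 1")
  structure(list(data = data, affine = affine, tr_s = tr_s),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> %d x %d x %d voxels, %d volumes, TR %.3g s, voxel %s mm\n",
              d[1], d[2], d[3], d[4], x$tr_s,
              paste(signif(voxel_sizes(x$affine), 3), collapse = " x ")))
  invisible(x)
}

#' Brain mask on a voxel grid
#'
#' @param data 3D logical array (`TRUE` = in brain).
#' @param affine 4x4 voxel-to-world transform shared with the images it masks.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(data, affine) {
  if (length(dim(data)) != 3L) stop("mask must be 3D")
  data <- array(as.logical(data), dim(data))
  if (!any(data)) stop("mask has no in-brain voxels")
  structure(list(data = data, affine = as_affine(affine)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s grid, %d in-mask voxels\n",
              paste(dim(x$data), collapse = " x "), sum(x$data)))
  invisible(x)
}

as_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps * 16)
    stop("affine is singular")
  unname(affine)
}

voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Convert between voxel indices and world (mm) coordinates
#'
#' `voxel_to_world()` maps 1-based voxel indices to mm; `world_to_voxel()`
#' is the (continuous) inverse.
#'
#' @param idx n x 3 matrix of 1-based voxel indices.
#' @param affine 4x4 voxel-to-world transform (NIfTI convention: 0-based).
#' @return n x 3 matrix of coordinates.
#' @export
voxel_to_world <- function(idx, affine) {
  idx <- rbind_matrix(idx)
  t(affine[1:3, 1:3] %*% t(idx - 1) + affine[1:3, 4])
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of world coordinates in mm.
#' @export
world_to_voxel <- function(xyz, affine) {
  xyz <- rbind_matrix(xyz)
  t(solve(affine[1:3, 1:3]) %*% (t(xyz) - affine[1:3, 4])) + 1
}

rbind_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

# grids must match exactly; never silently resample
check_same_grid <- function(dim_a, affine_a, dim_b, affine_b,
                            what = "objects") {
  if (!identical(as.integer(dim_a)[1:3], as.integer(dim_b)[1:3]))
    stop(what, " are on different grids: ",
         paste(dim_a[1:3], collapse = "x"), " vs ",
         paste(dim_b[1:3], collapse = "x"))
  if (max(abs(affine_a - affine_b)) > 1e-4)
    stop(what, " have different affines; refusing to combine ",
         "(resample explicitly instead)")
  invisible(TRUE)
}

#' Read a 4D BOLD NIfTI file
#'
#' @param path path to a 4D NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param tr_s optional TR override in seconds. Headers are often wrong; when
#'   the override disagrees with the header a warning is issued and the
#'   override wins.
#' @return A [bold4d] object.
#' @export
read_bold <- function(path, tr_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected 4D image, got ", length(d), "D: ", path)
  pd <- RNifti::pixdim(img)
  hdr_tr <- if (length(pd) >= 4) pd[4] else NA_real_
  if (is.null(tr_s)) {
    if (!is.finite(hdr_tr) || hdr_tr <= 0)
      stop("non-positive TR in header of ", path,
           "; pass tr_s explicitly")
    tr_s <- hdr_tr
  } else if (is.finite(hdr_tr) && hdr_tr > 0 &&
             abs(hdr_tr - tr_s) > 1e-6) {
    warning(sprintf("header TR %.4g s != supplied tr_s %.4g s; using %.4g",
                    hdr_tr, tr_s, tr_s))
  }
  bold4d(as.array(img)[, , , , drop = FALSE],
         affine = unclass(RNifti::xform(img)), tr_s = tr_s)
}

#' Write a 4D BOLD NIfTI file
#'
#' @param bold a [bold4d] object.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI on-disk type; `"double"` round-trips bit-exactly.
#' @return `path`, invisibly.
#' @export
write_bold <- function(bold, path, datatype = "double") {
  stopifnot(inherits(bold, "bold4d"))
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(voxel_sizes(bold$affine), bold$tr_s)
  RNifti::sform(img) <- structure(bold$affine, code = 2L)
  RNifti::qform(img) <- structure(bold$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read / write a 3D mask or map
#'
#' `read_mask()` interprets nonzero voxels as in-mask; `write_volume()` stores
#' any 3D array (maps, masks) with the given affine.
#'
#' @param path NIfTI file path.
#' @return [brain_mask] for `read_mask()`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected 3D mask, got ", length(dim(img)), "D: ", path)
  brain_mask(as.array(img) != 0, unclass(RNifti::xform(img)))
}

#' @rdname read_mask
#' @param vol 3D numeric/logical array.
#' @param affine 4x4 voxel-to-world transform.
#' @export
write_volume <- function(vol, affine, path) {
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- voxel_sizes(as_affine(affine))
  RNifti::sform(img) <- structure(as_affine(affine), code = 2L)
  RNifti::qform(img) <- structure(as_affine(affine), code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Spherical seed definition
#'
#' @param name unique text label, e.g. `"left vAI"`.
#' @param center_mni length-3 numeric, seed center in MNI mm.
#' @param radius_mm sphere radius in mm (>= 0).
#' @return An object of class `seed_spec`.
#' @export
seed_spec <- function(name, center_mni, radius_mm = 6) {
  stopifnot(is.character(name), length(name) == 1L,
            length(center_mni) == 3L, is.numeric(center_mni),
            is.numeric(radius_mm), length(radius_mm) == 1L, radius_mm >= 0)
  structure(list(name = name, center_mni = as.numeric(center_mni),
                 radius_mm = radius_mm),
            class = "seed_spec")
}

#' The six insular subdivision seeds
#'
#' 6-mm-radius spheres centered on the ventral anterior (vAI), dorsal
#' anterior (dAI) and posterior (pI) insula in each hemisphere. The right dAI
#' center is (35, 7, 3).
#'
#' @return Named list of six [seed_spec] objects.
#' @export
insula_seeds <- function() {
  centers <- list(
    "left vAI"  = c(-33,  13, -7),
    "right vAI" = c( 32,  10, -6),
    "left dAI"  = c(-38,   6,  2),
    "right dAI" = c( 35,   7,  3),
    "left pI"   = c(-38,  -6,  5),
    "right pI"  = c( 35, -11,  6)
  )
  out <- lapply(names(centers),
                function(nm) seed_spec(nm, centers[[nm]], 6))
  names(out) <- names(centers)
  out
}

#' Voxels inside a spherical seed
#'
#' Returns all in-mask voxels whose center lies within `radius_mm` of the
#' seed center (inclusive), distance measured in mm through the grid affine.
#'
#' @param seed a [seed_spec].
#' @param grid a [brain_mask] defining the grid and the in-brain voxels.
#' @return Integer matrix (n x 3) of 1-based voxel indices, with attributes
#'   `linear` (linear indices into the grid array) and `seed_name`.
#' @export
build_sphere_mask <- function(seed, grid) {
  stopifnot(inherits(seed, "seed_spec"), inherits(grid, "brain_mask"))
  d <- dim(grid$data)
  cv <- drop(world_to_voxel(seed$center_mni, grid$affine))
  if (any(cv < 0.5) || any(cv > d + 0.5))
    stop("seed '", seed$name, "' center lies outside the grid bounding box")
  # candidate cube around the center, then exact mm distance test
  vs <- voxel_sizes(grid$affine)
  r_vox <- ceiling(seed$radius_mm / vs) + 1L
  rng <- lapply(1:3, function(a)
    max(1L, floor(cv[a] - r_vox[a])):min(d[a], ceiling(cv[a] + r_vox[a])))
  cand <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  xyz <- voxel_to_world(cand, grid$affine)
  dist <- sqrt(rowSums((xyz - matrix(seed$center_mni, nrow(xyz), 3,
                                     byrow = TRUE))^2))
  keep <- dist <= seed$radius_mm + 1e-9
  cand <- cand[keep, , drop = FALSE]
  lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * d[1] * d[2]
  in_mask <- grid$data[lin]
  cand <- cand[in_mask, , drop = FALSE]
  lin <- lin[in_mask]
  if (nrow(cand) == 0L)
    stop("seed '", seed$name, "' contains no in-mask voxels")
  structure(cand, linear = as.integer(lin), seed_name = seed$name)
}

subject_columns <- c("id", "group", "age", "education", "co_ppm",
                     "smoking_years", "cigs_per_day", "ftcd")

#' Load a subject phenotype table
#'
#' Tab-separated, one row per subject, with columns `id`, `group`
#' (`smoker`/`control`), `age`, `education`, `co_ppm`, the smoker-only
#' variables `smoking_years`, `cigs_per_day`, `ftcd` (NA for controls), and
#' optionally `motion_path` / `nuisance_path` / `bold_path`.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` of typed subject records.
#' @export
load_subject_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("no subjects in ", path)
  missing_cols <- setdiff(subject_columns, names(tab))
  if (length(missing_cols))
    stop("subject table lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(tab$group), c("smoker", "control"))
  if (length(bad))
    stop("unknown group label(s) ", paste(sQuote(bad), collapse = ", "),
         "; permitted labels are 'smoker' and 'control'")
  num_cols <- setdiff(subject_columns, c("id", "group"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    if (any(is.na(v) & !is.na(tab[[cl]]) & tab[[cl]] != ""))
      stop("non-numeric values in column '", cl, "'")
    tab[[cl]] <- v
  }
  if (anyDuplicated(tab$id)) stop("duplicate subject ids")
  if (any(tab$co_ppm < 0, na.rm = TRUE)) stop("negative co_ppm")
  ctl <- tab$group == "control"
  smoker_only <- c("smoking_years", "cigs_per_day", "ftcd")
  if (any(!is.na(as.matrix(tab[ctl, smoker_only]))))
    stop("smoker-only columns must be empty for controls")
  message(sprintf("loaded %d subjects (%d smokers, %d controls)",
                  nrow(tab), sum(tab$group == "smoker"), sum(ctl)))
  tab
}

#' Write a subject phenotype table
#'
#' @param tab data.frame with the columns described in [load_subject_table].
#' @param path output TSV path.
#' @export
write_subject_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read confound series
#'
#' `read_motion()` expects a headerless 6-column TSV (3 translations in mm,
#' 3 rotations in degrees); `read_nuisance()` a 2-column TSV (white matter,
#' CSF mean signals).
#'
#' @param path TSV path.
#' @return Numeric matrix (time x series).
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  if (ncol(m) != 6L)
    stop("motion file must have 6 columns, found ", ncol(m), ": ", path)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' @rdname read_motion
#' @export
read_nuisance <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t"))
  if (ncol(m) != 2L)
    stop("nuisance file must have 2 columns (WM, CSF), found ",
         ncol(m), ": ", path)
  colnames(m) <- c("wm", "csf")
  m
}

write_series_tsv <- function(m, path) {
  utils::write.table(format(m, digits = 10, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bundle motion and tissue confounds
#'
#' @param motion time x 6 matrix (translations mm, rotations degrees).
#' @param wm,csf white-matter and CSF mean signals, same length as `motion`.
#' @return An object of class `confound_set` (time x 8 matrix).
#' @export
confound_set <- function(motion, wm, csf) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  if (length(wm) != nrow(motion) || length(csf) != nrow(motion))
    stop("confound series have unequal lengths")
  out <- cbind(motion, wm = as.numeric(wm), csf = as.numeric(csf))
  class(out) <- c("confound_set", class(out))
  out
}
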