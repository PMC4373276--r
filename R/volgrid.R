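#' @importFrom stats dist hclust cutree p.adjust pchisq qnorm runif rnorm sd
#' @importFrom utils read.delim write.table head
NULL

#' Voxel grid over a brain mask
#'
#' A `vol_grid` couples a boolean mask volume with a NIfTI-style affine
#' (voxel indices to millimetres) and precomputes the mm centers of all
#' in-mask voxels.  Every vectorized map in the package (activation rows,
#' z-maps, lattice node weights) is a plain numeric vector of length
#' `n_voxels`, ordered column-major over the in-mask voxels, so
#' [vectorize()] / [unvectorize()] are exact inverses on the mask.
#'
#' The affine follows the NIfTI convention: it maps *0-based* voxel
#' indices to mm coordinates.  [vox_to_mm()] and [mm_to_vox()] take and
#' return 1-based R array indices and handle the offset internally.
#'
#' @param mask logical (or coercible) 3D array; `TRUE` marks in-mask voxels.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @return an object of class `vol_grid` with fields `mask`, `affine`,
#'   `dim`, `n_voxels`, `vox_idx` (n_voxels x 3, 1-based array indices)
#'   and `centers` (n_voxels x 3, mm).
#' @export
vol_grid <- function(mask, affine) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  idx <- which(mask, arr.ind = TRUE)   # column-major order, matches mask[mask]
  centers <- t(affine %*% rbind(t(idx) - 1, 1))[, 1:3, drop = FALSE]
  structure(list(
    mask = mask, affine = affine, dim = dim(mask),
    n_voxels = nrow(idx), vox_idx = idx, centers = centers
  ), class = "vol_grid")
}

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf("<vol_grid> %s voxels in mask, shape %s, spacing %s mm\n",
              x$n_voxels, paste(x$dim, collapse = "x"),
              paste(signif(sqrt(colSums(x$affine[1:3, 1:3]^2)), 3), collapse = "x")))
  invisible(x)
}

#' Synthetic ellipsoid brain mask
#'
#' Builds a small ellipsoidal mask centered at the mm origin, a stand-in
#' for a template brain mask when no NIfTI mask is supplied (demo runs,
#' tests, the bundled synthetic corpus).  Semi-axes are 90% of the field
#' of view so a margin of out-of-mask voxels surrounds the "brain".
#'
#' @param dim integer 3-vector, grid shape in voxels.
#' @param spacing isotropic voxel size in mm.
#' @return a [vol_grid()].
#' @export
ellipsoid_grid <- function(dim = c(14L, 17L, 14L), spacing = 8) {
  dim <- as.integer(dim)
  affine <- diag(c(spacing, spacing, spacing, 1))
  affine[1:3, 4] <- -spacing * (dim - 1) / 2
  semi <- 0.9 * spacing * (dim - 1) / 2
  ax <- seq_len(dim[1]); ay <- seq_len(dim[2]); az <- seq_len(dim[3])
  mmx <- affine[1, 1] * (ax - 1) + affine[1, 4]
  mmy <- affine[2, 2] * (ay - 1) + affine[2, 4]
  mmz <- affine[3, 3] * (az - 1) + affine[3, 4]
  mask <- outer(outer((mmx / semi[1])^2, (mmy / semi[2])^2, "+"),
                (mmz / semi[3])^2, "+") <= 1
  vol_grid(mask, affine)
}

#' @rdname vol_grid
#' @param path path to a NIfTI mask volume; nonzero voxels form the mask.
#' @export
grid_from_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- arr[, , , 1]
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  vol_grid(arr != 0, matrix(as.numeric(aff), 4, 4))
}

#' Map between 1-based voxel indices and mm coordinates
#' @param grid a [vol_grid()].
#' @param ijk n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @return n x 3 matrix of mm coordinates (or voxel indices for
#'   [mm_to_vox()], real-valued; round to land on a voxel).
#' @export
vox_to_mm <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(grid$affine %*% rbind(t(ijk) - 1, 1))[, 1:3, drop = FALSE]
}

#' @rdname vox_to_mm
#' @param mm n x 3 matrix (or length-3 vector) of mm coordinates.
#' @export
mm_to_vox <- function(grid, mm) {
  mm <- matrix(mm, ncol = 3)
  t(solve(grid$affine) %*% rbind(t(mm), 1))[, 1:3, drop = FALSE] + 1
}

#' Test whether mm points fall on in-mask voxels
#' @inheritParams mm_to_vox
#' @return logical vector; `TRUE` where the nearest voxel is inside both
#'   the grid bounds and the mask.
#' @export
in_mask <- function(grid, mm) {
  v <- round(mm_to_vox(grid, mm))
  ok <- v[, 1] >= 1 & v[, 1] <= grid$dim[1] &
        v[, 2] >= 1 & v[, 2] <= grid$dim[2] &
        v[, 3] >= 1 & v[, 3] <= grid$dim[3]
  out <- logical(nrow(v))
  out[ok] <- grid$mask[v[ok, , drop = FALSE]]
  out
}

#' Stamp spheres around activation peaks
#'
#' Marks every in-mask voxel whose center lies within `radius` mm of any
#' peak.  This is how point coordinates become binary "activation
#' present" at the voxel level; peaks outside the mask contribute only
#' the in-mask portion of their sphere.
#'
#' @param peaks n x 3 matrix (or length-3 vector) of peak mm coordinates.
#' @param grid a [vol_grid()].
#' @param radius sphere radius in mm (>= 0); default 10.
#' @return binary integer vector of length `grid$n_voxels`.
#' @export
stamp_spheres <- function(peaks, grid, radius = 10) {
  stopifnot(radius >= 0)
  peaks <- matrix(peaks, ncol = 3)
  out <- logical(grid$n_voxels)
  r2 <- radius^2
  n_dead <- 0L
  for (i in seq_len(nrow(peaks))) {
    d2 <- (grid$centers[, 1] - peaks[i, 1])^2 +
          (grid$centers[, 2] - peaks[i, 2])^2 +
          (grid$centers[, 3] - peaks[i, 3])^2
    hit <- d2 <= r2
    if (!any(hit)) n_dead <- n_dead + 1L
    out <- out | hit
  }
  if (n_dead > 0L)
    warning(sprintf("%d peak(s) contributed no in-mask voxels", n_dead))
  as.integer(out)
}

#' Study-by-voxel binary activation matrix
#'
#' One row per study; a row is the union of stamped spheres of all peaks
#' that study reports.  Supplies the per-voxel counts for the 2x2
#' contingency tests in [reverse_inference_map()].
#'
#' @param tables a [corpus_tables()] object.
#' @param grid a [vol_grid()].
#' @param radius sphere radius in mm.
#' @return an `activation_matrix`: list with `studies` (sorted ids) and
#'   `values` (binary studies x n_voxels matrix).
#' @export
activation_matrix <- function(tables, grid, radius = 10) {
  co <- tables$coordinates
  if (nrow(co) == 0L) stop("coordinates table is empty")
  studies <- sort(unique(co$study_id))
  vals <- matrix(0L, nrow = length(studies), ncol = grid$n_voxels,
                 dimnames = list(studies, NULL))
  by_study <- split(seq_len(nrow(co)), co$study_id)
  for (s in studies) {
    rows <- by_study[[s]]
    pk <- as.matrix(co[rows, c("x", "y", "z")])
    keep <- stats::complete.cases(pk)
    if (!any(keep)) {
      message(sprintf("study %s has no parseable peaks; all-zero row", s))
      next
    }
    vals[s, ] <- suppressWarnings(stamp_spheres(pk[keep, , drop = FALSE], grid, radius))
  }
  structure(list(studies = studies, values = vals), class = "activation_matrix")
}

#' Flatten / restore volumes on the grid mask
#'
#' `vectorize()` extracts in-mask values (column-major over the mask);
#' `unvectorize()` writes them back into a full volume with out-of-mask
#' voxels set to 0.  They are exact inverses on the mask.
#'
#' @param volume 3D array with `grid$dim` shape.
#' @param grid a [vol_grid()].
#' @export
vectorize <- function(volume, grid) {
  if (!all(dim(volume) == grid$dim)) stop("volume shape does not match grid")
  as.numeric(volume[grid$mask])
}

#' @rdname vectorize
#' @param v numeric vector of length `grid$n_voxels`.
#' @export
unvectorize <- function(v, grid) {
  if (length(v) != grid$n_voxels)
    stop(sprintf("vector length %d does not match grid n_voxels %d",
                 length(v), grid$n_voxels))
  vol <- array(0, dim = grid$dim)
  vol[grid$mask] <- v
  vol
}

#' NIfTI I/O on a grid
#'
#' Volumes are written with the grid's affine (sform, code 2).  On read,
#' shape and affine are checked against the grid.
#'
#' @param v in-mask vector (or full volume) to write.
#' @param grid a [vol_grid()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(v, grid, path) {
  vol <- if (is.array(v) && length(dim(v)) == 3L) {
    if (!all(dim(v) == grid$dim)) stop("volume shape does not match grid")
    ifelse(grid$mask, v, 0)
  } else unvectorize(v, grid)
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @return `read_volume()` returns the in-mask vector.
#' @export
read_volume <- function(path, grid) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (!all(dim(arr)[1:3] == grid$dim)) stop("NIfTI shape does not match grid")
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  if (max(abs(aff - grid$affine)) > 1e-4) stop("NIfTI affine does not match grid")
  vectorize(array(arr, dim = grid$dim), grid)
}

#' @rdname write_volume
#' @export
write_mask <- function(grid, path) {
  write_volume(array(as.numeric(grid$mask), grid$dim), grid, path)
}
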