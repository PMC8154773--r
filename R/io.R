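#' Read a 3D volume from NIfTI
#'
#' Reads a NIfTI-1 file and converts it to the package's internal
#' convention: axes reordered to RAS (left-to-right, posterior-to-anterior,
#' inferior-to-superior) so that spacing is positive along every axis, with
#' the origin stored as the world corner of voxel (0,0,0).  World
#' coordinates of any anatomical point are unchanged by the reordering.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param mask logical; if `TRUE` the volume is returned as a [mask3d()]
#'   (values must be 0/1).
#' @return a [vol3d()] (or [mask3d()]).
#' @export
read_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path, internal = FALSE)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D volume, got %d dimensions in %s",
                 length(d), path))
  if (RNifti::orientation(img) != "RAS")
    RNifti::orientation(img) <- "RAS"
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("missing or invalid voxel spacing in NIfTI header")
  # NIfTI maps the 0-based index to the voxel centre; shift to the corner.
  origin <- aff[1:3, 4L] - 0.5 * spacing
  values <- array(as.numeric(img), d)
  if (mask) mask3d(values, spacing, origin) else vol3d(values, spacing, origin)
}

#' Write a volume to NIfTI
#'
#' Masks are written as uint8 with values {0,1}; scalar volumes as float64.
#' The geometry round-trips through [read_volume()] to 1e-6 mm.
#'
#' @param volume a [vol3d()] or [mask3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  is_mask <- inherits(volume, "mask3d") || is.logical(volume$values)
  values <- volume$values
  if (is_mask) values <- array(as.integer(values), dim(values))
  img <- RNifti::asNifti(values,
                         datatype = if (is_mask) "uint8" else "double",
                         internal = FALSE)
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4L] <- volume$origin + 0.5 * volume$spacing
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume onto a target grid under a rigid transform
#'
#' For every voxel centre `x` of the target grid the source volume is
#' sampled at `T(x)`; `transform` therefore maps target (fixed) world
#' coordinates to source (moving) world coordinates, so passing the result
#' of [register_rigid()] resamples the moving image into the fixed frame.
#' Scalar volumes use trilinear interpolation, masks nearest-neighbour (the
#' output value set is preserved).
#'
#' @param volume source [vol3d()] or [mask3d()].
#' @param transform a `rigid3d` / `rigid3d_matrix`; default identity.
#' @param target a `vol3d` (or `mask3d`) defining the output grid; default
#'   the source grid.
#' @param fill value assigned to target voxels that map outside the source
#'   field of view (default 0).
#' @return a volume/mask on the target grid.
#' @export
resample <- function(volume, transform = rigid3d(), target = volume,
                     fill = 0) {
  pts <- transform_points(transform, all_voxel_centers(target))
  idx <- world_to_voxel(volume, pts)
  nn <- inherits(volume, "mask3d") || is.logical(volume$values)
  vals <- interp_volume(volume$values, idx, nearest = nn, fill = fill)
  out <- array(vals, dim(target$values))
  if (nn) mask3d(out != 0, target$spacing, target$origin)
  else vol3d(out, target$spacing, target$origin)
}

# Trilinear / nearest interpolation at fractional 0-based voxel indices.
interp_volume <- function(arr, idx, nearest = FALSE, fill = 0) {
  d <- dim(arr)
  if (nearest) {
    i <- round(idx[, 1L]); j <- round(idx[, 2L]); k <- round(idx[, 3L])
    ok <- i >= 0 & i <= d[1L] - 1L & j >= 0 & j <= d[2L] - 1L &
      k >= 0 & k <= d[3L] - 1L
    out <- rep(as.numeric(fill), nrow(idx))
    lin <- 1L + i[ok] + d[1L] * (j[ok] + d[2L] * k[ok])
    out[ok] <- as.numeric(arr[lin])
    return(out)
  }
  i0 <- floor(idx[, 1L]); j0 <- floor(idx[, 2L]); k0 <- floor(idx[, 3L])
  fx <- idx[, 1L] - i0; fy <- idx[, 2L] - j0; fz <- idx[, 3L] - k0
  ok <- i0 >= 0 & i0 <= d[1L] - 1L & j0 >= 0 & j0 <= d[2L] - 1L &
    k0 >= 0 & k0 <= d[3L] - 1L
  # clamp the +1 neighbour so points in the last half-voxel interpolate flat
  out <- rep(as.numeric(fill), nrow(idx))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  i1 <- pmin(i0 + 1, d[1L] - 1L); j1 <- pmin(j0 + 1, d[2L] - 1L)
  k1 <- pmin(k0 + 1, d[3L] - 1L)
  at <- function(i, j, k) as.numeric(arr[1L + i + d[1L] * (j + d[2L] * k)])
  out[ok] <-
    at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(i1, j0, k0) * fx * (1 - fy) * (1 - fz) +
    at(i0, j1, k0) * (1 - fx) * fy * (1 - fz) +
    at(i1, j1, k0) * fx * fy * (1 - fz) +
    at(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
    at(i1, j0, k1) * fx * (1 - fy) * fz +
    at(i0, j1, k1) * (1 - fx) * fy * fz +
    at(i1, j1, k1) * fx * fy * fz
  out
}
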