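#' 3D scalar volume with voxel geometry
#'
#' A `vol3d` is the package's basic container: a 3D numeric array together
#' with voxel spacing (mm) and the world position of the corner of voxel
#' `(0,0,0)`.  Axes are ordered (x in-plane, y in-plane, z through-slice);
#' voxel indices are 0-based and voxel `i` covers the half-open world box
#' `[origin + i*d, origin + (i+1)*d)`, so its centre sits at
#' `origin + (i + 0.5)*d`.
#'
#' @param values numeric 3D array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world coordinate (mm) of the corner of
#'   voxel (0,0,0).
#' @return An object of class `vol3d`.
#' @export
vol3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  if (any(!is.finite(values)))
    stop("volume values must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "vol3d")
}

#' Binary mask on the grid of a volume
#'
#' A `mask3d` shares the geometry (shape, spacing, origin) of its owning
#' volume and stores one logical per voxel.
#'
#' @param values logical (or 0/1 numeric) 3D array.
#' @inheritParams vol3d
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!is.logical(values)) {
    if (!all(values %in% c(0, 1)))
      stop("mask values must be logical or 0/1")
    values <- array(as.logical(values), dim(values))
  }
  out <- vol3d(array(0, dim(values)), spacing, origin)
  out$values <- values
  class(out) <- c("mask3d", "vol3d")
  out
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1L], paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  if (is.logical(x$values))
    cat(sprintf("  foreground voxels: %d\n", sum(x$values)))
  else
    cat(sprintf("  value range: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.vol3d <- function(x) dim(x$values)

#' Voxel volume in mm^3
#' @param x a `vol3d` or `mask3d`.
#' @return scalar, product of the spacings.
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

grid_compatible <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_compatible <- function(a, b, what = "inputs") {
  if (!grid_compatible(a, b))
    stop(sprintf("%s are not grid-compatible (shape/spacing/origin differ)",
                 what))
  invisible(TRUE)
}

#' Same-grid companion constructors
#'
#' `like_volume()` / `like_mask()` wrap an array in the geometry of a
#' reference volume.
#' @param values array matching `dim(ref)`.
#' @param ref a `vol3d` supplying spacing and origin.
#' @return a `vol3d` (resp. `mask3d`).
#' @export
like_volume <- function(values, ref) {
  if (!identical(dim(values), dim(ref$values)))
    stop("array shape does not match reference grid")
  vol3d(values, ref$spacing, ref$origin)
}

#' @rdname like_volume
#' @export
like_mask <- function(values, ref) {
  if (!identical(dim(values), dim(ref$values)))
    stop("array shape does not match reference grid")
  mask3d(values, ref$spacing, ref$origin)
}

#' World coordinates of voxel centres
#'
#' Converts 0-based voxel indices to the world coordinates (mm) of the voxel
#' centres under the package's half-open box convention.
#'
#' @param x a `vol3d`.
#' @param idx n-by-3 matrix of 0-based voxel indices (may be fractional).
#' @return n-by-3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(x, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx + 0.5, 2L, x$spacing, "*"), 2L, x$origin, "+")
}

#' @rdname voxel_to_world
#' @param xyz n-by-3 matrix of world coordinates (mm).
#' @return For `world_to_voxel`, n-by-3 matrix of fractional 0-based indices.
#' @export
world_to_voxel <- function(x, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  sweep(sweep(xyz, 2L, x$origin, "-"), 2L, x$spacing, "/") - 0.5
}

#' World centre of a volume's grid
#' @param x a `vol3d`.
#' @return length-3 world coordinate of the geometric centre of the grid.
#' @export
grid_center <- function(x) x$origin + dim(x$values) * x$spacing / 2

# Matrix of voxel-centre world coordinates for every voxel, column-major
# (same linear order as the values array).
all_voxel_centers <- function(x) {
  d <- dim(x$values)
  i <- rep.int(seq_len(d[1L]) - 1L, d[2L] * d[3L])
  j <- rep.int(rep(seq_len(d[2L]) - 1L, each = d[1L]), d[3L])
  k <- rep(seq_len(d[3L]) - 1L, each = d[1L] * d[2L])
  cbind((i + 0.5) * x$spacing[1L] + x$origin[1L],
        (j + 0.5) * x$spacing[2L] + x$origin[2L],
        (k + 0.5) * x$spacing[3L] + x$origin[3L])
}
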