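#' Rigid 6-parameter transform
#'
#' Three rotation angles in degrees (about the world x, y, z axes, applied in
#' the order z, then y, then x when mapping a point) and three translations
#' in mm.  Rotation is about an explicit centre `center` in world
#' coordinates: `T(p) = R (p - c) + c + t`.  Used as the mapping from
#' fixed-image world coordinates to moving-image world coordinates, the ITK
#' resampling convention.
#'
#' @param angles_deg length-3 rotations (degrees) about x, y, z.
#' @param translation_mm length-3 translation in mm.
#' @param center length-3 rotation centre in world mm (default the origin).
#' @return An object of class `rigid3d`.
#' @export
rigid3d <- function(angles_deg = c(0, 0, 0), translation_mm = c(0, 0, 0),
                    center = c(0, 0, 0)) {
  angles_deg <- as.numeric(angles_deg)
  translation_mm <- as.numeric(translation_mm)
  center <- as.numeric(center)
  stopifnot(length(angles_deg) == 3L, length(translation_mm) == 3L,
            length(center) == 3L,
            all(is.finite(c(angles_deg, translation_mm, center))))
  structure(list(angles_deg = angles_deg, translation_mm = translation_mm,
                 center = center),
            class = "rigid3d")
}

#' @export
print.rigid3d <- function(x, ...) {
  cat(sprintf("<rigid3d> rot (%s) deg, trans (%s) mm, centre (%s) mm\n",
              paste(signif(x$angles_deg, 4), collapse = ", "),
              paste(signif(x$translation_mm, 4), collapse = ", "),
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1L]); sx <- sin(a[1L])
  cy <- cos(a[2L]); sy <- sin(a[2L])
  cz <- cos(a[3L]); sz <- sin(a[3L])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L)
  rx %*% ry %*% rz
}

#' Apply a rigid transform to world points
#' @param transform a `rigid3d`.
#' @param xyz n-by-3 matrix of world coordinates (mm).
#' @return n-by-3 matrix of transformed coordinates.
#' @export
apply_rigid <- function(transform, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  r <- rotation_matrix(transform$angles_deg)
  p <- sweep(xyz, 2L, transform$center, "-") %*% t(r)
  sweep(p, 2L, transform$center + transform$translation_mm, "+")
}

#' Invert a rigid transform
#'
#' The inverse has the same rotation centre; composing a transform with its
#' inverse is the identity to machine precision.
#' @param transform a `rigid3d`.
#' @return the inverse `rigid3d`-equivalent mapping, returned as a
#'   matrix-backed transform of class `rigid3d_matrix`.
#' @export
invert_rigid <- function(transform) {
  r <- rotation_matrix(transform$angles_deg)
  # inverse: p = R'(q - c - t) + c
  affine_transform(t(r),
                   transform$center -
                     t(r) %*% (transform$center + transform$translation_mm))
}

#' Compose two transforms
#'
#' Returns the transform equivalent to applying `b` first, then `a`
#' (`(a %then% b)(p) = a(b(p))` reads `compose_rigid(a, b)`).
#' @param a,b transforms (`rigid3d` or `rigid3d_matrix`).
#' @return a `rigid3d_matrix`.
#' @export
compose_rigid <- function(a, b) {
  ma <- as_affine(a); mb <- as_affine(b)
  m <- ma$r %*% mb$r
  v <- ma$r %*% mb$v + ma$v
  affine_transform(m, v)
}

# Internal matrix form: T(p) = r p + v
affine_transform <- function(r, v) {
  structure(list(r = r, v = as.numeric(v)), class = "rigid3d_matrix")
}

as_affine <- function(x) {
  if (inherits(x, "rigid3d_matrix")) return(x)
  r <- rotation_matrix(x$angles_deg)
  v <- x$center + x$translation_mm - r %*% x$center
  affine_transform(r, as.numeric(v))
}

#' Recover angle/translation parameters from a matrix-backed transform
#'
#' Expresses any rigid transform as three Euler angles (degrees, x-y-z
#' convention matching [rigid3d()]) plus a translation about the given
#' centre.  Valid for |pitch| < 90 degrees, which covers the small offsets
#' handled by this package.
#' @param transform a `rigid3d` or `rigid3d_matrix`.
#' @param center rotation centre (world mm) for the parameterisation.
#' @return a `rigid3d`.
#' @export
as_rigid3d <- function(transform, center = c(0, 0, 0)) {
  m <- as_affine(transform)
  r <- m$r
  b <- asin(max(-1, min(1, r[1L, 3L])))
  a <- atan2(-r[2L, 3L], r[3L, 3L])
  g <- atan2(-r[1L, 2L], r[1L, 1L])
  angles <- c(a, b, g) * 180 / pi
  tr <- m$v - center + r %*% center
  rigid3d(angles, as.numeric(tr), center)
}

transform_points <- function(transform, xyz) {
  if (inherits(transform, "rigid3d_matrix")) {
    xyz <- matrix(as.numeric(xyz), ncol = 3L)
    sweep(xyz %*% t(transform$r), 2L, transform$v, "+")
  } else {
    apply_rigid(transform, xyz)
  }
}

#' Translation / rotation magnitude of a transform
#'
#' Summarises how far a transform is from the identity: the norm of the
#' translation of the grid centre of a reference volume, and the total
#' rotation angle in degrees.  Used to verify registration accuracy and
#' inverse consistency.
#' @param transform a `rigid3d` or `rigid3d_matrix`.
#' @return named numeric: `trans_mm`, `rot_deg`.
#' @export
rigid_magnitude <- function(transform) {
  m <- as_affine(transform)
  tr <- sum(diag(m$r))
  ang <- acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
  # translation measured as displacement of the rotation-invariant point 0
  c(trans_mm = sqrt(sum(m$v^2)), rot_deg = ang)
}
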