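#' Hessian eigenvalues of a smoothed volume
#'
#' Computes the scale-normalised Hessian (gamma = 1: second derivatives
#' multiplied by sigma^2) of the Gaussian-smoothed volume at scale
#' `sigma_mm`, with all derivatives taken in mm, and returns the three
#' eigenvalues per voxel ordered by increasing absolute value.  Through-
#' slice derivative components are down-weighted by the in-plane/through-
#' slice spacing ratio: at 3 mm slices the sheet is undersampled along z
#' and unweighted z-curvature would be dominated by slice-to-slice jumps.
#'
#' @param volume a [vol3d()].
#' @param sigma_mm Gaussian scale in mm; must be at least the in-plane
#'   spacing.
#' @param z_weight weight on Hessian components involving z; default the
#'   spacing ratio `mean(in-plane)/through-slice`.
#' @return object of class `eigen_field`: arrays `l1`, `l2`, `l3` with
#'   `|l1| <= |l2| <= |l3|`, plus `sigma_mm` and the grid geometry.
#' @export
hessian_eigen <- function(volume, sigma_mm, z_weight = NULL) {
  sp <- volume$spacing
  if (sigma_mm < max(sp[1:2]))
    stop("sigma_mm must be at least the in-plane voxel spacing")
  if (is.null(z_weight)) z_weight <- mean(sp[1:2]) / sp[3L]
  sig_vox <- c(sigma_mm / sp[1L], sigma_mm / sp[2L], sigma_mm / sp[3L])
  sm <- gaussian_smooth(volume$values, sig_vox)
  d1 <- function(a, ax) deriv_axis(a, ax, sp[ax])
  gx <- d1(sm, 1L); gy <- d1(sm, 2L); gz <- d1(sm, 3L)
  s2 <- sigma_mm^2
  hxx <- d1(gx, 1L) * s2
  hyy <- d1(gy, 2L) * s2
  hzz <- d1(gz, 3L) * s2 * z_weight^2
  hxy <- d1(gx, 2L) * s2
  hxz <- d1(gx, 3L) * s2 * z_weight
  hyz <- d1(gy, 3L) * s2 * z_weight
  ev <- sym3_eigenvalues(hxx, hyy, hzz, hxy, hxz, hyz)
  structure(list(l1 = ev$l1, l2 = ev$l2, l3 = ev$l3, sigma_mm = sigma_mm,
                 spacing = sp, origin = volume$origin,
                 dim = dim(volume$values)),
            class = "eigen_field")
}

# Closed-form eigenvalues of symmetric 3x3 matrices, vectorised over
# arrays; returns them sorted by |.| ascending.
sym3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > .Machine$double.eps
  b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
  b12 <- a12 / p; b13 <- a13 / p; b23 <- a23 / p
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(1, pmax(-1, detb / 2))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!ok] <- q[!ok]; e2[!ok] <- q[!ok]; e3[!ok] <- q[!ok]
  # sort the triple by absolute value per voxel
  d <- dim(a11)
  m <- cbind(as.numeric(e1), as.numeric(e2), as.numeric(e3))
  am <- abs(m)
  o1 <- max.col(-am, ties.method = "first")
  o3 <- max.col(am, ties.method = "last")
  same <- o1 == o3           # all equal magnitudes
  o3[same] <- (o1[same] %% 3L) + 1L
  o2 <- 6L - o1 - o3
  n <- nrow(m)
  l1 <- m[cbind(seq_len(n), o1)]
  l2 <- m[cbind(seq_len(n), o2)]
  l3 <- m[cbind(seq_len(n), o3)]
  list(l1 = array(l1, d), l2 = array(l2, d), l3 = array(l3, d))
}

#' Plate-likeness (sheetness) weight map
#'
#' Frangi-style sheetness for dark plates on a bright background, evaluated
#' on fibrous-cluster voxels outside the muscle envelope (the fascia lata
#' evidence field).  For each scale the weight is 0 where `l3 <= 0`
#' (polarity gate: a dark sheet has positive principal curvature) and
#' otherwise
#' `exp(-R_sheet^2 / 2 alpha^2) * exp(-R_blob^2 / 2 beta^2) *
#'  (1 - exp(-S^2 / 2 c^2))`
#' with `R_sheet = |l2|/|l3|`, `R_blob = |l1|/sqrt(|l2 l3|)` (0 where the
#' denominator vanishes), and `S` the Frobenius norm of the eigenvalues.
#' The final weight is the maximum over the scale set, zeroed outside
#' `fibrous & !me`.
#'
#' @param eig an `eigen_field` or a list of them (one per scale).
#' @param fibrous fibrous-cluster [mask3d()].
#' @param me muscle-envelope [mask3d()].
#' @param alpha sheet-vs-tube sensitivity (default 0.5).
#' @param beta blob suppression (default 0.5).
#' @param c structureness cutoff; `NULL` (default) uses a quarter of the
#'   maximum `S` over the support, per scale (with the support restricted
#'   to fibrous voxels outside ME the maximum is close to the sheet's own
#'   `S`, so half-max would cap the sheetness of the true fascia well
#'   below 1).
#' @return a [mask3d()]-compatible [vol3d()] with values in [0, 1]
#'   (class `weight_map`).
#' @export
plate_weight <- function(eig, fibrous, me, alpha = 0.5, beta = 0.5,
                         c = NULL) {
  if (inherits(eig, "eigen_field")) eig <- list(eig)
  stopifnot_compatible(fibrous, me, "fibrous and ME masks")
  support <- fibrous$values & !me$values
  out <- array(0, dim(fibrous$values))
  for (ef in eig) {
    if (!identical(ef$dim, dim(fibrous$values)))
      stop("eigen field and masks are not grid-compatible")
    l1 <- ef$l1; l2 <- ef$l2; l3 <- ef$l3
    s2 <- l1^2 + l2^2 + l3^2
    cs <- if (is.null(c)) {
      smax <- sqrt(max(s2[support], 0))
      if (smax <= 0) 1 else smax / 4
    } else c
    r_sheet <- abs(l2) / pmax(abs(l3), .Machine$double.eps)
    den <- sqrt(abs(l2 * l3))
    r_blob <- ifelse(den > 0, abs(l1) / pmax(den, .Machine$double.eps), 0)
    w <- exp(-r_sheet^2 / (2 * alpha^2)) * exp(-r_blob^2 / (2 * beta^2)) *
      (1 - exp(-s2 / (2 * cs^2)))
    w[l3 <= 0] <- 0
    out <- pmax(out, w)
  }
  out[!support] <- 0
  res <- like_volume(out, fibrous)
  class(res) <- c("weight_map", class(res))
  res
}

#' Fascia-lata weight map of a volume
#'
#' Convenience wrapper: Hessian eigenvalues at each scale of `scales_mm`
#' fed through [plate_weight()].
#' @param volume bias-corrected T1w [vol3d()].
#' @param fibrous,me masks as in [plate_weight()].
#' @param scales_mm Gaussian scale set in mm (default 1.0, 1.5, 2.5).
#' @param ... passed to [plate_weight()].
#' @return a `weight_map`.
#' @export
fascia_weights <- function(volume, fibrous, me,
                           scales_mm = c(1.0, 1.5, 2.5), ...) {
  eig <- lapply(scales_mm, function(s) hessian_eigen(volume, s))
  plate_weight(eig, fibrous, me, ...)
}

#' Close the fascia lata surface by a second level set
#'
#' A second contracting front starts at the thigh surface (the only closed
#' surface outside the muscle envelope the pipeline owns) and shrinks
#' inward with stopping function `g = 1 - w`, where `w` is the plate-
#' likeness weight dilated by one in-plane voxel to bridge single-voxel
#' evidence gaps.  The muscle envelope is locked: the front can never
#' enter it, so the converged region always satisfies
#' `ME` \eqn{\subseteq} `IF` \eqn{\subseteq} `thigh`.  Fibrous fragments
#' that do not form a closed surface around ME (e.g. the saphenous-fascia
#' decoy) are bypassed: the front flows around them, they end up as
#' disconnected debris and are removed.  With zero fascia evidence the
#' front collapses onto ME and the result is flagged degenerate.
#'
#' @param me muscle-envelope [mask3d()].
#' @param weights `weight_map` from [plate_weight()]/[fascia_weights()].
#' @param thigh thigh [mask3d()].
#' @param params a [level_set_params()].
#' @return object of class `fl_surface`: `if_voi` ([mask3d()]), `contours`
#'   (per-slice list of n-by-2 matrices of 0-based in-plane voxel
#'   coordinates tracing the FL), and `degenerate` (logical flag).
#' @export
fl_surface <- function(me, weights, thigh,
                       params = level_set_params(g_stop = 0.3)) {
  stopifnot_compatible(me, thigh, "ME and thigh masks")
  stopifnot_compatible(weights, thigh, "weights and thigh mask")
  if (!all(me$values <= thigh$values))
    stop("ME must be contained in the thigh mask")
  w <- EBImage::dilate(weights$values, disk_brush(1L))
  frozen <- (1 - w) < params$g_stop
  degenerate <- max(weights$values) <= 0
  u <- contract_front(thigh$values, frozen, params, locked = me$values)
  # the VOI is the region *enclosed by* the FL: remove the fascia band the
  # front froze on (undilated evidence), keeping the inner surface
  band <- (1 - weights$values) < params$g_stop & !me$values
  u <- (u & thigh$values & !band) | me$values
  u <- largest_component_3d(u)
  u <- open_slices(u, 1L) | me$values
  u <- largest_component_3d(u)
  u <- fill_holes_slices(u)
  u <- (u & thigh$values) | me$values
  if_voi <- mask3d(u, thigh$spacing, thigh$origin)
  if (!degenerate && sum(u) <= sum(me$values))
    degenerate <- TRUE
  if (degenerate)
    warning("no usable fascia evidence: IF region collapsed onto the ",
            "muscle envelope")
  contours <- lapply(seq_len(dim(u)[3L]), function(k)
    trace_boundary(u[, , k]))
  structure(list(if_voi = if_voi, contours = contours,
                 degenerate = degenerate),
            class = "fl_surface")
}

#' @export
print.fl_surface <- function(x, ...) {
  n <- sum(vapply(x$contours, function(ct) nrow(ct) > 0L, logical(1)))
  cat(sprintf("<fl_surface> IF VOI %d voxels, contours on %d slices%s\n",
              sum(x$if_voi$values), n,
              if (x$degenerate) " [degenerate: IF = ME]" else ""))
  invisible(x)
}

# Moore-neighbour boundary tracing of the largest region in a 2D mask.
# Returns an n-by-2 matrix of 0-based (x, y) voxel coordinates ordered
# along the closed contour (empty matrix if the slice is empty).
trace_boundary <- function(slice) {
  if (!any(slice)) return(matrix(numeric(0), 0L, 2L))
  d <- dim(slice)
  pad <- matrix(FALSE, d[1L] + 2L, d[2L] + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L)] <- slice
  # start: lexicographically smallest foreground pixel (column-major)
  start <- which(pad)[1L]
  sx <- (start - 1L) %% (d[1L] + 2L) + 1L
  sy <- (start - 1L) %/% (d[1L] + 2L) + 1L
  # 8 neighbours clockwise starting from west
  nb <- matrix(c(-1L, 0L, -1L, -1L, 0L, -1L, 1L, -1L, 1L, 0L, 1L, 1L,
                 0L, 1L, -1L, 1L), nrow = 2L)
  path <- matrix(integer(0), 0L, 2L)
  cur <- c(sx, sy)
  entered_from <- 1L   # pretend we entered heading east, backtrack = west
  path <- rbind(path, cur)
  repeat {
    found <- FALSE
    for (step in 0:7) {
      k <- (entered_from - 1L + step) %% 8L + 1L
      cand <- cur + nb[, k]
      if (pad[cand[1L], cand[2L]]) {
        # next backtrack direction: neighbour index pointing back to `cur`
        entered_from <- (k + 4L) %% 8L + 1L
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break                     # isolated pixel
    if (all(cur == c(sx, sy))) break
    path <- rbind(path, cur)
    if (nrow(path) > 4L * sum(pad)) break # safety
  }
  path - 2L   # back to 0-based coordinates of the unpadded slice
}
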