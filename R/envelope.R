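#' Level-set parameters
#'
#' Parameters of the discrete (morphological) geodesic-active-contour
#' scheme used for the muscle envelope and the fascia surface.  The scheme
#' is the threshold-dynamics approximation of the Caselles geodesic active
#' contour: per iteration the front contracts by one in-plane voxel
#' (balloon force -1) except where the edge-stopping function `g` falls
#' below `g_stop` (a strong edge), and an in-plane morphological opening is
#' applied every `smooth_every` iterations as the curvature term.  Each
#' update is a subset of the previous front, so the scheme is
#' unconditionally stable and the enclosed volume non-increasing.
#'
#' @param g_stop edge-stopping threshold in (0,1): front voxels with
#'   `g < g_stop` are frozen.
#' @param curvature_weight 0 disables curvature smoothing; >= 1 gives the
#'   in-plane opening radius.
#' @param smooth_every apply the curvature smoothing every this many
#'   iterations.
#' @param max_iter iteration cap.
#' @param conv_tol convergence threshold: fraction of grid voxels changed
#'   per iteration below which (held for `conv_patience` iterations) the
#'   evolution stops.
#' @param conv_patience number of consecutive quiet iterations required.
#' @param edge_quantile quantile of the gradient magnitude (among edge
#'   candidates) at which the edge map equals `edge_value`.
#' @param edge_value value of the edge map at the calibration quantile.
#' @return a list of class `level_set_params`.
#' @export
level_set_params <- function(g_stop = 0.2, curvature_weight = 1,
                             smooth_every = 5L, max_iter = 300L,
                             conv_tol = 1e-4, conv_patience = 5L,
                             edge_quantile = 0.9, edge_value = 0.1) {
  stopifnot(g_stop > 0, g_stop < 1, max_iter >= 1,
            edge_quantile > 0, edge_quantile < 1,
            edge_value > 0, edge_value < 1)
  structure(list(g_stop = g_stop, curvature_weight = curvature_weight,
                 smooth_every = as.integer(smooth_every),
                 max_iter = as.integer(max_iter), conv_tol = conv_tol,
                 conv_patience = as.integer(conv_patience),
                 edge_quantile = edge_quantile, edge_value = edge_value),
            class = "level_set_params")
}

#' Edge-stopping map from fuzzy memberships
#'
#' Builds the geodesic-active-contour stopping function from the muscle
#' membership field: `g = exp(-s * |grad u_muscle|)` with gradients taken
#' in mm (per-axis spacing) after light in-plane Gaussian smoothing.  The
#' sharpness `s` is calibrated so that `g` equals `edge_value` (default
#' 0.1) at the `edge_quantile` (default 90th percentile) of the gradient
#' magnitude among edge candidates (voxels whose gradient exceeds 10% of
#' the maximum).  The result is strictly positive, 1 in homogeneous
#' regions, and monotone decreasing in the gradient magnitude.
#'
#' @param members a `membership_map` from [fcm()].
#' @param cluster cluster whose membership drives the edge map (default 3,
#'   the muscle cluster).
#' @param params a [level_set_params()].
#' @param presmooth_mm in-plane Gaussian sigma (mm) applied to the
#'   membership field before differentiation.
#' @return a [vol3d()] with values in (0, 1].
#' @export
edge_map <- function(members, cluster = 3L, params = level_set_params(),
                     presmooth_mm = 0.5) {
  u <- membership_volume(members, cluster)
  sp <- u$spacing
  sig <- c(presmooth_mm / sp[1L], presmooth_mm / sp[2L], 0)
  sm <- gaussian_smooth(u$values, sig)
  gmag <- gradient_magnitude(sm, sp)
  gmax <- max(gmag)
  if (gmax < .Machine$double.eps)
    return(like_volume(array(1, dim(u$values)), u))
  cand <- gmag[gmag > 0.1 * gmax]
  ref <- stats::quantile(cand, params$edge_quantile, names = FALSE)
  s <- -log(params$edge_value) / ref
  like_volume(exp(-s * gmag), u)
}

# Core contraction loop shared by the two level-set stages.
# Front `u` shrinks in-plane from its initial configuration; voxels where
# `frozen` holds are never removed once reached; `locked` (optional) is a
# region the front can never enter (it is kept inside u throughout).
contract_front <- function(u, frozen, params, locked = NULL) {
  n_grid <- length(u)
  quiet <- 0L
  for (it in seq_len(params$max_iter)) {
    u_new <- erode_slices(u, 1L) | (u & frozen)
    if (params$curvature_weight >= 1 && it %% params$smooth_every == 0L) {
      u_new <- open_slices(u_new, as.integer(params$curvature_weight)) |
        (u_new & frozen)
    }
    if (!is.null(locked)) u_new <- u_new | locked
    changed <- sum(xor(u_new, u))
    u <- u_new
    if (changed <= params$conv_tol * n_grid) {
      quiet <- quiet + 1L
      if (quiet >= params$conv_patience) break
    } else quiet <- 0L
  }
  u
}

#' Muscle envelope by geodesic active contour
#'
#' Evolves a contracting front from the thigh boundary inward, driven by
#' the edge map derived from the muscle membership field, and returns the
#' region enclosed by the converged front: the tightly fitting envelope of
#' the muscle ensemble (ME).  Intramuscular structures (fat streaks, the
#' femur) are enclosed; isolated muscle-labelled islands in the SAT (e.g.
#' veins) end up disconnected from the main body and are discarded, so
#' they lie outside ME.
#'
#' @param members `membership_map` from [fcm()].
#' @param thigh thigh [mask3d()] (skin removed).
#' @param params a [level_set_params()].
#' @param g optional precomputed edge map ([vol3d()]); default
#'   `edge_map(members, 3, params)`.
#' @param tighten final in-plane erosion in voxels (default 1): the front
#'   freezes on the outer skirt of the boundary-gradient band, about one
#'   voxel outside the muscle surface, so one erosion restores the tight
#'   fit.
#' @return a [mask3d()]: single 3D connected component, hole-filled per
#'   slice, contained in the thigh.
#' @export
muscle_envelope <- function(members, thigh, params = level_set_params(),
                            g = NULL, tighten = 1L) {
  if (is.null(g)) g <- edge_map(members, 3L, params)
  stopifnot_compatible(g, thigh, "edge map and thigh mask")
  frozen <- g$values < params$g_stop
  u <- contract_front(thigh$values, frozen, params)
  u <- u & thigh$values
  if (!any(u)) stop("muscle envelope collapsed to an empty region")
  u <- largest_component_3d(u)
  u <- open_slices(u, 1L)
  u <- largest_component_3d(u)
  if (!any(u)) stop("muscle envelope collapsed to an empty region")
  u <- fill_holes_slices(u)
  if (tighten >= 1L) {
    u <- erode_slices(u, as.integer(tighten))
    u <- largest_component_3d(u)
    u <- fill_holes_slices(u)
  }
  if (!any(u)) stop("muscle envelope collapsed to an empty region")
  u <- u & thigh$values
  mask3d(u, thigh$spacing, thigh$origin)
}
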