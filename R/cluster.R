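#' Fuzzy c-means clustering of voxel intensities
#'
#' Standard fuzzy c-means on the scalar intensity of every voxel in `mask`:
#' memberships `u_ik = [ sum_j (|x_k - v_i| / |x_k - v_j|)^(2/(m-1)) ]^-1`
#' and centres `v_i = sum_k u_ik^m x_k / sum_k u_ik^m`, iterated until the
#' largest centre shift falls below `tol` (relative to the intensity range).
#' A voxel coinciding with a centre gets membership 1 there.  Centres are
#' initialised at fixed intensity percentiles of the mask, so the result is
#' deterministic; identical intensities are pooled, which makes each
#' iteration O(#unique values).
#'
#' @param volume a [vol3d()].
#' @param mask [mask3d()] of voxels to cluster (default: whole grid).
#' @param k number of clusters (default 4: bone/background, fibrous,
#'   muscle, adipose tissue).
#' @param m fuzziness exponent (> 1, default 2).
#' @param tol convergence tolerance on centre shift as a fraction of the
#'   intensity range (default 1e-4).
#' @param max_iter iteration cap (default 200); non-convergence warns.
#' @param init_probs percentiles (0-1) for centre initialisation.
#' @return object of class `membership_map`: `centers` (ascending),
#'   `memberships` (voxels-in-mask by k, rows sum to 1), `mask`, `m`,
#'   `objective` (per-iteration values of `sum u^m d^2`), `converged`.
#' @export
fcm <- function(volume, mask = NULL, k = 4L, m = 2, tol = 1e-4,
                max_iter = 200L,
                init_probs = c(0.05, 0.35, 0.65, 0.95)) {
  if (is.null(mask))
    mask <- like_mask(array(TRUE, dim(volume$values)), volume)
  stopifnot_compatible(volume, mask, "volume and mask")
  if (m <= 1) stop("fuzziness exponent m must be > 1")
  sel <- which(mask$values)
  x <- volume$values[sel]
  ux <- sort(unique(x))
  if (length(ux) < k)
    stop(sprintf("mask holds %d distinct intensities; need >= k = %d",
                 length(ux), k))
  if (length(init_probs) != k)
    init_probs <- seq(0.05, 0.95, length.out = k)
  rng <- diff(range(x))
  # pool identical intensities: cluster the unique values with counts
  cnt <- tabulate(match(x, ux))
  v <- as.numeric(stats::quantile(x, probs = init_probs, names = FALSE))
  v <- make_distinct(v, rng)
  expo <- 2 / (m - 1)
  objective <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d2 <- outer(ux, v, function(a, b) (a - b)^2)        # n_unique x k
    u <- memberships_from_d2(d2, expo)
    um <- u^m * cnt
    v_new <- colSums(um * ux) / colSums(um)
    objective <- c(objective, sum(um * d2))
    if (max(abs(v_new - v)) < tol * rng) {
      v <- v_new; converged <- TRUE; break
    }
    v <- v_new
  }
  if (!converged)
    warning("fuzzy c-means did not converge within max_iter")
  ord <- order(v)
  d2 <- outer(ux, v[ord], function(a, b) (a - b)^2)
  u <- memberships_from_d2(d2, expo)
  full_u <- u[match(x, ux), , drop = FALSE]
  structure(list(centers = v[ord], memberships = full_u, mask = mask,
                 voxel_index = sel, m = m, objective = objective,
                 converged = converged),
            class = "membership_map")
}

# u_ik from squared distances, handling voxels that sit on a centre.
memberships_from_d2 <- function(d2, expo) {
  k <- ncol(d2)
  zero <- d2 < .Machine$double.eps
  onz <- rowSums(zero) > 0L
  # general update on strictly positive distances
  p <- d2^(expo / 2)                      # |x - v|^expo
  u <- 1 / (p * rowSums(1 / p))
  if (any(onz))
    u[onz, ] <- zero[onz, , drop = FALSE] /
      rowSums(zero[onz, , drop = FALSE])
  u
}

make_distinct <- function(v, rng) {
  eps <- max(rng, 1) * 1e-6
  for (i in seq_along(v)[-1L])
    if (v[i] <= v[i - 1L]) v[i] <- v[i - 1L] + eps
  v
}

#' @export
print.membership_map <- function(x, ...) {
  cat(sprintf("<membership_map> k = %d, m = %g, %d voxels, %s\n",
              length(x$centers), x$m, nrow(x$memberships),
              if (x$converged) sprintf("converged in %d iterations",
                                       length(x$objective))
              else "NOT converged"))
  cat("  centers:", paste(signif(x$centers, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Membership of one cluster as a volume
#'
#' Expands the per-voxel membership of cluster `cluster` to a full-grid
#' [vol3d()] (zero outside the clustered mask).
#' @param members a `membership_map`.
#' @param cluster cluster index (1 = lowest-intensity centre).
#' @return a [vol3d()].
#' @export
membership_volume <- function(members, cluster) {
  ref <- members$mask
  out <- array(0, dim(ref$values))
  out[members$voxel_index] <- members$memberships[, cluster]
  like_volume(out, ref)
}

# Tissue names in ascending centre-intensity order.
TISSUE_LEVELS <- c("bone_background", "fibrous", "muscle", "AT")

#' Harden fuzzy memberships into tissue labels
#'
#' Takes the argmax over memberships per voxel; ties break toward the
#' lower-intensity cluster.  Clusters are named by ascending centre
#' intensity: bone/background < fibrous < muscle < adipose tissue, so the
#' labelling is invariant to any permutation of cluster indices.
#'
#' @param members a `membership_map` from [fcm()] (k = 4).
#' @return object of class `tissue_labels`: `labels` (integer array,
#'   0 = outside mask, 1..k by ascending intensity), `tissues` (names per
#'   level), `centers`, `mask`.
#' @export
harden <- function(members) {
  ord <- order(members$centers)
  u <- members$memberships[, ord, drop = FALSE]
  members$centers <- members$centers[ord]
  k <- ncol(u)
  lab <- max.col(u, ties.method = "first")
  ref <- members$mask
  labels <- array(0L, dim(ref$values))
  labels[members$voxel_index] <- lab
  tissues <- if (k == 4L) TISSUE_LEVELS else paste0("cluster", seq_len(k))
  structure(list(labels = labels, tissues = tissues,
                 centers = members$centers, mask = ref,
                 spacing = ref$spacing, origin = ref$origin),
            class = "tissue_labels")
}

#' @export
print.tissue_labels <- function(x, ...) {
  cat("<tissue_labels>\n")
  tab <- table(factor(x$labels[x$labels > 0L],
                      levels = seq_along(x$tissues), labels = x$tissues))
  print(tab)
  invisible(x)
}

#' Mask of one tissue class
#' @param labels a `tissue_labels`.
#' @param tissue tissue name (one of `labels$tissues`) or level index.
#' @return a [mask3d()].
#' @export
tissue_mask <- function(labels, tissue) {
  lev <- if (is.character(tissue)) match(tissue, labels$tissues)
  else as.integer(tissue)
  if (is.na(lev) || lev < 1L || lev > length(labels$tissues))
    stop("unknown tissue class")
  mask3d(labels$labels == lev, labels$spacing, labels$origin)
}

#' Extract the thigh surface mask
#'
#' The thigh is the complement of the background: bone/background-labelled
#' voxels connected to the volume border form the true background, the rest
#' is foreground.  The foreground is closed slice-wise (in-plane disk),
#' reduced to its largest 3D connected component, hole-filled per slice
#' (air bubbles in SAT are absorbed), and finally the skin is removed: an
#' outer rind of `rind_voxels` in-plane voxels is deleted where its
#' intensity exceeds the skin threshold (midpoint of the muscle and AT
#' cluster centres by default).
#'
#' @param labels a `tissue_labels` from [harden()].
#' @param volume the (bias-corrected) intensity volume.
#' @param rind_voxels thickness of the candidate skin rind (default 2).
#' @param skin_threshold intensity above which rind voxels are treated as
#'   skin; default `(center_muscle + center_AT)/2`.
#' @param close_radius in-plane closing radius in voxels (default 2).
#' @return a [mask3d()] of the thigh without skin (single 3D component).
#' @export
thigh_surface <- function(labels, volume, rind_voxels = 2L,
                          skin_threshold = NULL, close_radius = 2L) {
  if (is.null(skin_threshold)) {
    if (length(labels$centers) < 4L)
      stop("need 4 cluster centres to derive the skin threshold")
    skin_threshold <- mean(labels$centers[3:4])
  }
  bg <- labels$labels == 1L
  # background = bone/background voxels 3D-connected to the volume border
  border_bg <- bg
  border_bg[2:(dim(bg)[1] - 1), 2:(dim(bg)[2] - 1), ] <- FALSE
  lab_bg <- label_components_3d(bg)
  border_ids <- setdiff(unique(lab_bg[border_bg]), 0L)
  background <- array(lab_bg %in% border_ids, dim(bg))
  fg <- !background
  fg <- close_slices(fg, close_radius)
  fg <- largest_component_3d(fg)
  if (!any(fg)) stop("no foreground component found")
  fg <- fill_holes_slices(fg)
  # skin removal: bright outer rind
  rind <- fg & !erode_slices(fg, rind_voxels)
  skin <- rind & volume$values > skin_threshold
  fg <- fg & !skin
  fg <- largest_component_3d(fg)
  mask3d(fg, labels$spacing, labels$origin)
}

#' Segment the femur
#'
#' Among bone/background-labelled components fully interior to the thigh,
#' picks the one nearest the thigh centroid (the cortical shell), then
#' fills it per slice so the enclosed marrow is included.  Fails if no
#' interior bone component exists.
#'
#' @param labels a `tissue_labels`.
#' @param thigh thigh [mask3d()] from [thigh_surface()].
#' @param min_voxels components smaller than this are ignored (noise).
#' @return a [mask3d()] of the femur (cortex + marrow), contained in the
#'   thigh.
#' @export
segment_femur <- function(labels, thigh, min_voxels = 50L) {
  interior <- erode_slices(thigh$values, 1L)
  bone <- labels$labels == 1L & interior
  lab <- label_components_3d(bone)
  n <- max(lab)
  if (n == 0L) stop("no interior bone component: femur not found")
  d <- dim(lab)
  centroid <- colMeans(arrayInd(which(thigh$values), d))
  best <- NULL; best_dist <- Inf
  for (i in seq_len(n)) {
    vox <- which(lab == i)
    if (length(vox) < min_voxels) next
    ci <- colMeans(arrayInd(vox, d))
    di <- sqrt(sum(((ci - centroid) *
                      c(thigh$spacing[1:2], thigh$spacing[3L]))[1:2]^2))
    if (di < best_dist) { best_dist <- di; best <- i }
  }
  if (is.null(best)) stop("no interior bone component: femur not found")
  femur <- lab == best
  femur <- fill_holes_slices(close_slices(femur, 1L))
  femur <- femur & thigh$values
  mask3d(femur, labels$spacing, labels$origin)
}
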