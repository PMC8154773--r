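#' Correct multiplicative intensity inhomogeneity
#'
#' Removes a smooth multiplicative bias field from a T1w volume before
#' clustering.  The field is modelled as `exp(P(x))` with `P` a 3D
#' polynomial of total order `order` in grid coordinates normalised to
#' [-1, 1].  The fit alternates (a) a coarse tissue-class assignment by
#' k-means on the current log intensities with (b) a least-squares
#' polynomial fit of the log-residuals (log intensity minus assigned class
#' centre), until the field update falls below `tol` or `max_iter` is
#' reached.  The reconstructed field is normalised to mean 1 over the fit
#' mask, so corrected intensities keep the input's overall scale.
#'
#' @param volume a [vol3d()] T1w volume.
#' @param mask [mask3d()] of voxels used for the fit (typically the thigh);
#'   must be non-empty.
#' @param order total polynomial order of the field (>= 1, default 3).
#' @param k number of coarse intensity classes used during fitting
#'   (default 6: background/clipped, cortical bone, fibrous, muscle, skin,
#'   adipose).
#' @param tol convergence tolerance on the maximum absolute change of the
#'   log-field between iterations (default 1e-3).
#' @param max_iter maximum number of alternations (default 20).
#' @param max_fit_voxels voxel budget for the least-squares fit; the mask is
#'   subsampled deterministically beyond this size.
#' @return a list with `volume` (corrected [vol3d()]) and `model` (class
#'   `bias_model`: `order`, `coefficients`, `field` as a [vol3d()],
#'   `iterations`, `converged`).  Non-convergence returns the last iterate
#'   with a warning.
#' @export
correct_bias <- function(volume, mask, order = 3L, k = 6L, tol = 1e-3,
                         max_iter = 20L, max_fit_voxels = 40000L) {
  if (!inherits(volume, "vol3d")) stop("`volume` must be a vol3d")
  stopifnot_compatible(volume, mask, "volume and mask")
  sel <- which(mask$values)
  if (length(sel) == 0L) stop("fit mask is empty")
  if (order < 1L) stop("`order` must be >= 1")

  vals <- volume$values[sel]
  floor_val <- max(max(vals) * 1e-4, 1e-8)
  logv <- log(pmax(vals, floor_val))

  basis <- polynomial_basis(dim(volume$values), order)
  fit_idx <- if (length(sel) > max_fit_voxels)
    sel[round(seq(1L, length(sel), length.out = max_fit_voxels))] else sel
  a_fit <- basis[fit_idx, , drop = FALSE]
  logv_fit <- log(pmax(volume$values[fit_idx], floor_val))

  coef_total <- numeric(ncol(basis))
  log_field_fit <- numeric(length(fit_idx))
  converged <- FALSE
  iter <- 0L
  damping <- 0.7
  for (iter in seq_len(max_iter)) {
    corrected <- logv_fit - log_field_fit
    kk <- min(k, length(unique(corrected)))
    km <- run_seeded(97L, suppressWarnings(
      stats::kmeans(corrected, centers = kk, nstart = 10L, iter.max = 50L)))
    resid <- corrected - km$centers[km$cluster, 1L]
    # robust fit: thin or rare tissues far from every class centre would
    # otherwise bend the polynomial; trim gross residuals
    keep <- abs(resid - stats::median(resid)) <=
      3 * stats::mad(resid) + 1e-12
    fit <- stats::lm.fit(a_fit[keep, , drop = FALSE], resid[keep])
    upd <- damping * fit$coefficients
    upd[is.na(upd)] <- 0
    coef_total <- coef_total + upd
    delta <- a_fit %*% upd
    log_field_fit <- log_field_fit + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("bias correction did not converge within max_iter; ",
            "returning last iterate")

  log_field <- array(as.numeric(basis %*% coef_total), dim(volume$values))
  field <- exp(log_field)
  # the polynomial is unconstrained outside the fit mask; clamp the field
  # to its in-mask range so uncovered regions are never amplified
  rng_mask <- range(field[sel])
  field <- pmin(pmax(field, rng_mask[1L]), rng_mask[2L])
  field <- field / mean(field[sel])
  field_vol <- like_volume(field, volume)
  out <- like_volume(volume$values / field, volume)
  model <- structure(list(order = as.integer(order),
                          coefficients = coef_total,
                          field = field_vol,
                          mask = mask,
                          iterations = iter,
                          converged = converged),
                     class = "bias_model")
  list(volume = out, model = model)
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("<bias_model> order %d, %d iterations, %s\n", x$order,
              x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  field range on grid: [%.4f, %.4f]\n",
              min(x$field$values), max(x$field$values)))
  invisible(x)
}

#' Polynomial design matrix over a grid
#'
#' All monomials `x^a y^b z^c` with `a+b+c <= order` (constant included) in
#' per-axis coordinates normalised to [-1, 1], one row per voxel in
#' column-major order.
#' @param d grid dimensions (length 3).
#' @param order total polynomial order.
#' @return numeric matrix with `prod(d)` rows.
#' @export
polynomial_basis <- function(d, order) {
  nx <- norm_coord(d[1L]); ny <- norm_coord(d[2L]); nz <- norm_coord(d[3L])
  x <- rep.int(nx, d[2L] * d[3L])
  y <- rep.int(rep(ny, each = d[1L]), d[3L])
  z <- rep(nz, each = d[1L] * d[2L])
  cols <- list()
  for (a in 0:order) for (b in 0:(order - a)) for (cc in 0:(order - a - b))
    cols[[sprintf("x%dy%dz%d", a, b, cc)]] <- x^a * y^b * z^cc
  do.call(cbind, cols)
}
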