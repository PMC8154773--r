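# Separable array filtering used by the edge map and the Hessian filter.

# Shift a 3D array by `by` voxels along axis `ax` with replicate padding.
shift_array <- function(arr, ax, by) {
  if (by == 0L) return(arr)
  d <- dim(arr)
  n <- d[ax]
  src <- pmin(pmax(seq_len(n) - by, 1L), n)
  switch(ax,
         arr[src, , , drop = FALSE],
         arr[, src, , drop = FALSE],
         arr[, , src, drop = FALSE])
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve along one axis with a symmetric kernel (replicate padding).
convolve_axis <- function(arr, ax, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(arr))
  for (t in seq_along(kernel))
    out <- out + kernel[t] * shift_array(arr, ax, t - r - 1L)
  out
}

# Separable Gaussian smoothing; sigma_vox per axis in voxel units
# (0 disables the axis).
gaussian_smooth <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    if (sigma_vox[ax] > 1e-6)
      arr <- convolve_axis(arr, ax, gaussian_kernel(sigma_vox[ax]))
  }
  arr
}

# Central-difference first derivative along an axis, in 1/mm.
deriv_axis <- function(arr, ax, spacing_mm) {
  (shift_array(arr, ax, -1L) - shift_array(arr, ax, 1L)) / (2 * spacing_mm)
}

# Gradient magnitude in 1/mm of a scalar array.
gradient_magnitude <- function(arr, spacing) {
  gx <- deriv_axis(arr, 1L, spacing[1L])
  gy <- deriv_axis(arr, 2L, spacing[2L])
  gz <- deriv_axis(arr, 3L, spacing[3L])
  sqrt(gx^2 + gy^2 + gz^2)
}
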