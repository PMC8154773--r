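#' Trim edge slices from a mask
#'
#' Zeroes the first and last `n` slices of an analysis mask; segmentation
#' quality at the stack edges is limited (bias correction and 3D filters
#' lose support there), so quantification omits them.
#'
#' @param mask a [mask3d()] with more than `2n` slices.
#' @param n slices to drop at each end (default 3).
#' @return the trimmed [mask3d()].
#' @export
trim_slices <- function(mask, n = 3L) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  d <- dim(mask$values)
  if (d[3L] <= 2L * n)
    stop(sprintf("stack has %d slices; need more than %d to trim %d each",
                 d[3L], 2L * n, n))
  if (n == 0L) return(mask)
  out <- mask$values
  out[, , c(seq_len(n), (d[3L] - n + 1L):d[3L])] <- FALSE
  mask3d(out, mask$spacing, mask$origin)
}

#' Intermuscular adipose tissue volume in a region
#'
#' Sums the adipose-cluster voxels inside `region` (femur excluded) and
#' converts to cm^3.  Using the intra-fascia VOI gives IMAT_FL; the same
#' call with the muscle envelope gives IMAT_ME, so the two differ only by
#' the region.
#'
#' @param labels `tissue_labels` from [harden()].
#' @param region analysis [mask3d()] (typically trimmed).
#' @param femur femur [mask3d()] (`NULL` for none).
#' @return volume in cm^3.
#' @export
imat_volume <- function(labels, region, femur = NULL) {
  at_level <- match("AT", labels$tissues)
  ref <- region
  if (!is.null(femur)) {
    stopifnot_compatible(region, femur, "region and femur masks")
    sel <- region$values & !femur$values
  } else sel <- region$values
  if (!identical(dim(labels$labels), dim(region$values)))
    stop("labels and region are not grid-compatible")
  n_at <- sum(labels$labels[sel] == at_level)
  n_at * prod(region$spacing) / 1000
}

#' Rigid registration of two volumes
#'
#' Estimates the 6-parameter rigid transform mapping fixed-image world
#' coordinates to moving-image world coordinates by maximising the mutual
#' information of the two intensity distributions, evaluated at voxels of
#' the fixed mask (the moving image is interpolated linearly).  The
#' translation is initialised from the mask centroids; optimisation is
#' derivative-free (Nelder-Mead) in two resolutions (a subsample, then the
#' full sample budget).
#'
#' @param fixed,moving [vol3d()] volumes.
#' @param fixed_mask,moving_mask thigh [mask3d()]s on the two grids.
#' @param bins histogram bins per axis of the joint histogram.
#' @param max_samples fixed-mask sample budget for the fine level; thin
#'   structures (fascia, fat streaks, cortical bone) carry the rotational
#'   information, so the fine level needs a dense sample.
#' @param maxit Nelder-Mead iteration budget for the coarse level (the
#'   fine level uses `maxit/2`).
#' @return a `rigid3d` (rotation about the fixed grid centre) with the
#'   final negative-MI value in attribute `metric`.
#' @export
register_rigid <- function(fixed, fixed_mask, moving, moving_mask,
                           bins = 32L, max_samples = 120000L,
                           maxit = 400L) {
  stopifnot_compatible(fixed, fixed_mask, "fixed volume and mask")
  stopifnot_compatible(moving, moving_mask, "moving volume and mask")
  if (!any(fixed_mask$values) || !any(moving_mask$values))
    stop("both thigh masks must be non-empty")
  center <- grid_center(fixed)

  d <- dim(fixed$values)
  idx <- which(fixed_mask$values)
  co <- arrayInd(idx, d) - 1L
  pts_all <- voxel_to_world(fixed, co)
  vals_all <- fixed$values[idx]

  # centroid initialisation for the translation
  cf <- colMeans(pts_all)
  im <- which(moving_mask$values)
  cm <- colMeans(voxel_to_world(moving, arrayInd(im, dim(moving$values)) - 1L))
  par0 <- c(0, 0, 0, cm - cf)

  mrange <- range(moving$values)
  frange <- range(vals_all)
  metric <- function(par, pts, fvals) {
    tr <- rigid3d(par[1:3], par[4:6], center)
    mv <- interp_volume(moving$values, world_to_voxel(moving,
                                                      apply_rigid(tr, pts)),
                        fill = NA)
    ok <- !is.na(mv)
    if (sum(ok) < 100L) return(1e6)
    -mutual_information(fvals[ok], mv[ok], frange, mrange, bins)
  }
  run_level <- function(par, n_samples, maxit) {
    take <- if (length(idx) > n_samples)
      round(seq(1L, length(idx), length.out = n_samples)) else
        seq_along(idx)
    pts <- pts_all[take, , drop = FALSE]
    fvals <- vals_all[take]
    stats::optim(par, metric, pts = pts, fvals = fvals,
                 method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10,
                                parscale = c(2, 2, 2, 2, 2, 2)))
  }
  o1 <- run_level(par0, min(20000L, max_samples), maxit)
  o2 <- run_level(o1$par, max_samples, max(100L, maxit %/% 2L))
  if (!is.finite(o2$value) || o2$value >= 1e6)
    stop("registration diverged: no overlap between the volumes")
  out <- rigid3d(o2$par[1:3], o2$par[4:6], center)
  attr(out, "metric") <- o2$value
  out
}

# Shannon mutual information of two samples via a joint histogram with
# fixed value ranges.  Samples are spread over the four neighbouring bins
# with bilinear (Parzen) weights, which removes the binning discontinuities
# that would otherwise dominate the metric near the optimum.
mutual_information <- function(a, b, arange, brange, bins) {
  ua <- pmin(bins - 1 + 1e-9,
             pmax(1e-9, (a - arange[1L]) / diff(arange) * bins + 0.5)) - 0.5
  ub <- pmin(bins - 1 + 1e-9,
             pmax(1e-9, (b - brange[1L]) / diff(brange) * bins + 0.5)) - 0.5
  ua <- pmin(pmax(ua, 0), bins - 1); ub <- pmin(pmax(ub, 0), bins - 1)
  ia0 <- pmin(floor(ua), bins - 2); ib0 <- pmin(floor(ub), bins - 2)
  fa <- ua - ia0; fb <- ub - ib0
  acc <- numeric(bins * bins)
  add <- function(ia, ib, w)
    acc <<- acc + tabulate_weighted(ia * bins + ib + 1L, w, bins * bins)
  add(ia0, ib0, (1 - fa) * (1 - fb))
  add(ia0 + 1, ib0, fa * (1 - fb))
  add(ia0, ib0 + 1, (1 - fa) * fb)
  add(ia0 + 1, ib0 + 1, fa * fb)
  p <- acc / sum(acc)
  pm <- matrix(p, bins, bins)
  px <- rowSums(pm); py <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / (px[row(pm)[nz]] * py[col(pm)[nz]])))
}

tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  s <- rowsum(w, idx, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

#' Muscle/adipose threshold from the log-scaled FF histogram
#'
#' Histograms the fat-fraction intensities (0--1000 scale) inside the
#' intra-fascia VOI, maps counts through `log(1 + count)`, smooths with a
#' centred moving average, finds the two most prominent modes (the low-FF
#' muscle mode and the high-FF adipose mode) and returns the centre of the
#' minimum bin between them.  A histogram without two separated modes sets
#' the `unimodal` flag and suggests the fallback threshold 500.
#'
#' @param ff FF [vol3d()] (values 0--1000; FF% = intensity/10).
#' @param if_voi intra-fascia [mask3d()] on the FF grid.
#' @param bin_width histogram bin width in intensity units (default 10,
#'   i.e. 1 % FF).
#' @param smooth_window moving-average window in bins (odd, default 5).
#' @param min_mode_separation minimal separation of the two modes in
#'   intensity units (default 100, i.e. 10 % FF).
#' @param min_prominence minimal rise of the secondary mode above the
#'   inter-mode valley, in log(1+count) units (default 1, about a factor
#'   e in counts); guards against reading noise bumps as a second tissue
#'   mode.
#' @return object of class `mt_threshold`: `threshold`, `unimodal`
#'   (failure flag), `bin_centers`, `log_counts`, `smoothed`, `modes`.
#' @export
mt_threshold <- function(ff, if_voi, bin_width = 10, smooth_window = 5L,
                         min_mode_separation = 100, min_prominence = 1) {
  stopifnot_compatible(ff, if_voi, "FF volume and IF VOI")
  vals <- ff$values[if_voi$values]
  if (length(vals) == 0L) stop("IF VOI is empty on the FF grid")
  breaks <- seq(0, 1000 + bin_width, by = bin_width)
  cnt <- tabulate(pmin(length(breaks) - 1L,
                       pmax(1L, floor(vals / bin_width) + 1L)),
                  nbins = length(breaks) - 1L)
  centers <- breaks[-length(breaks)] + bin_width / 2
  lg <- log1p(cnt)
  sm <- moving_average(lg, smooth_window)
  # local maxima of the smoothed log-histogram
  n <- length(sm)
  is_max <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                sm[2:(n - 1)] >= sm[3:n], FALSE)
  peaks <- which(is_max)
  res <- list(bin_centers = centers, log_counts = lg, smoothed = sm)
  if (length(peaks) >= 2L) {
    p1 <- peaks[which.max(sm[peaks])]
    far <- peaks[abs(centers[peaks] - centers[p1]) >= min_mode_separation]
    # the secondary mode must rise clearly above the inter-mode valley
    far <- far[vapply(far, function(p)
      sm[p] - min(sm[min(p, p1):max(p, p1)]) >= min_prominence,
      logical(1))]
    if (length(far) > 0L) {
      p2 <- far[which.max(sm[far])]
      lo <- min(p1, p2); hi <- max(p1, p2)
      between <- sm[lo:hi]
      # empty inter-mode bins form a flat minimum plateau; take its middle
      # so the threshold is the centre of the gap, not its first bin
      flat <- which(between <= min(between) + 1e-12)
      valley <- lo + flat[ceiling(length(flat) / 2)] - 1L
      res$threshold <- centers[valley]
      res$unimodal <- FALSE
      res$modes <- sort(centers[c(p1, p2)])
      class(res) <- "mt_threshold"
      return(res)
    }
  }
  warning("FF histogram has no two separated modes; using fallback ",
          "threshold 500")
  res$threshold <- 500
  res$unimodal <- TRUE
  res$modes <- numeric(0)
  class(res) <- "mt_threshold"
  res
}

moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) w <- w + 1L
  half <- w %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2L))[
    (half + 1L):(half + length(x))]
}

#' @export
print.mt_threshold <- function(x, ...) {
  cat(sprintf("<mt_threshold> %g (FF %.1f%%)%s\n", x$threshold,
              x$threshold / 10,
              if (x$unimodal) " [unimodal histogram: fallback]" else ""))
  invisible(x)
}

#' Mean fat fraction of muscle tissue
#'
#' Mean FF intensity over the muscle-tissue mask divided by 10: the
#' scanner scale 0--1000 encodes FF 0.0--100.0 %.
#'
#' @param ff FF [vol3d()].
#' @param mt_mask muscle-tissue [mask3d()] (IF voxels below the MT
#'   threshold, femur excluded).
#' @return FF in percent.
#' @export
ff_mt <- function(ff, mt_mask) {
  stopifnot_compatible(ff, mt_mask, "FF volume and MT mask")
  if (!any(mt_mask$values)) stop("muscle-tissue mask is empty")
  mean(ff$values[mt_mask$values]) / 10
}

#' Assemble a quantification report
#'
#' @param volume_total_cm3 IF volume minus femur (cm^3).
#' @param imat_fl_cm3,imat_me_cm3 IMAT within the FL / within ME (cm^3).
#' @param ff_mt_pct muscle-tissue fat fraction (%), `NA` without FF data.
#' @param mt_threshold MT threshold on the 0--1000 scale (`NA` without FF).
#' @param slices_analyzed slice count after trimming.
#' @return object of class `quant_report`.
#' @export
quant_report <- function(volume_total_cm3, imat_fl_cm3, imat_me_cm3,
                         ff_mt_pct = NA_real_, mt_threshold = NA_real_,
                         slices_analyzed = NA_integer_) {
  stopifnot(volume_total_cm3 >= 0, imat_fl_cm3 >= 0, imat_me_cm3 >= 0,
            imat_fl_cm3 <= volume_total_cm3 + 1e-9,
            is.na(ff_mt_pct) || (ff_mt_pct >= 0 && ff_mt_pct <= 100))
  structure(list(volume_total_cm3 = volume_total_cm3,
                 imat_fl_cm3 = imat_fl_cm3,
                 imat_me_cm3 = imat_me_cm3,
                 delta_imat_cm3 = imat_fl_cm3 - imat_me_cm3,
                 ff_mt_pct = ff_mt_pct,
                 mt_threshold = mt_threshold,
                 slices_analyzed = slices_analyzed),
            class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat("<quant_report>\n")
  cat(sprintf("  Volume_total : %8.2f cm^3\n", x$volume_total_cm3))
  cat(sprintf("  IMAT_FL      : %8.2f cm^3\n", x$imat_fl_cm3))
  cat(sprintf("  IMAT_ME      : %8.2f cm^3\n", x$imat_me_cm3))
  cat(sprintf("  dIMAT        : %8.2f cm^3\n", x$delta_imat_cm3))
  cat(sprintf("  FF_MT        : %8.2f %%\n", x$ff_mt_pct))
  cat(sprintf("  MT threshold : %8.1f (0-1000)\n", x$mt_threshold))
  cat(sprintf("  slices       : %d\n", x$slices_analyzed))
  invisible(x)
}
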