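test_that("slice trimming keeps 28 of 34 slices and validates its inputs", {
  m34 <- mask3d(array(TRUE, c(4L, 4L, 34L)))
  tr <- trim_slices(m34, 3L)
  kept <- which(apply(tr$values, 3L, any))
  expect_length(kept, 28L)
  expect_equal(kept, 4:31)
  expect_identical(trim_slices(m34, 0L)$values, m34$values)
  expect_error(trim_slices(mask3d(array(TRUE, c(4L, 4L, 6L))), 3L),
               "slices")
})

test_that("IMAT volume arithmetic: 1000 AT voxels at 0.5x0.5x3 mm are
           0.75 cm^3", {
  d <- c(20L, 20L, 5L)
  labels <- array(3L, d)          # muscle everywhere
  at_idx <- seq_len(1000L)
  labels[at_idx] <- 4L            # AT
  lab <- structure(list(labels = labels, tissues = fasciata:::TISSUE_LEVELS,
                        centers = c(10, 160, 420, 820),
                        spacing = c(0.5, 0.5, 3), origin = c(0, 0, 0)),
                   class = "tissue_labels")
  region <- mask3d(array(TRUE, d), spacing = c(0.5, 0.5, 3))
  expect_equal(imat_volume(lab, region), 0.75)
  none <- mask3d(array(FALSE, d), spacing = c(0.5, 0.5, 3))
  labels0 <- labels; labels0[] <- 3L
  lab0 <- lab; lab0$labels <- labels0
  expect_equal(imat_volume(lab0, region), 0)
  # femur exclusion removes AT voxels under the femur mask
  femur <- mask3d(array(seq_len(prod(d)) <= 500L, d),
                  spacing = c(0.5, 0.5, 3))
  expect_equal(imat_volume(lab, region, femur), 500 * 0.75 / 1000)
})

test_that("self-registration returns the identity within 0.1 mm / 0.1 deg", {
  s <- small_stages()
  tr <- register_rigid(s$bc$volume, s$thigh, s$bc$volume, s$thigh)
  expect_lt(max(abs(tr$angles_deg)), 0.1)
  expect_lt(max(abs(tr$translation_mm)), 0.1)
})

test_that("registration recovers the phantom's known rigid offset and is
           inverse-consistent", {
  s <- small_stages()
  ph <- s$ph
  ff_mask <- like_mask(
    fasciata:::largest_component_3d(
      fasciata:::fill_holes_slices(
        fasciata:::close_slices(ph$ff$values > 100, 2L))), ph$ff)
  ab <- register_rigid(s$bc$volume, s$thigh, ph$ff, ff_mask)
  truth <- ph$truth$rigid_offset
  est <- as_rigid3d(ab, center = truth$center)
  # the reduced-field fixture carries less rotational information than the
  # full-size phantom (which the acceptance suite holds to 0.5 mm/0.5 deg)
  expect_lt(max(abs(est$angles_deg - truth$angles_deg)), 1.0)
  expect_lt(max(abs(est$translation_mm - truth$translation_mm)), 1.0)

  ba <- register_rigid(ph$ff, ff_mask, s$bc$volume, s$thigh)
  comp <- compose_rigid(ab, ba)
  # displacement of points in the thigh under the composed map
  pts <- voxel_to_world(s$bc$volume,
                        arrayInd(which(s$thigh$values), dim(s$thigh$values))
                        [seq(1, sum(s$thigh$values), length.out = 200), ] - 1)
  moved <- fasciata:::transform_points(comp, pts)
  expect_lt(max(sqrt(rowSums((moved - pts)^2))), 1.5)
})

test_that("mt_threshold finds the valley of a known two-Gaussian mixture
           within 2 bins of the numeric oracle", {
  set.seed(5)
  n <- 20000L
  vals <- c(stats::rnorm(n, 70, 30), stats::rnorm(n, 800, 30))
  vals <- pmin(1000, pmax(0, vals))
  d <- c(40L, 40L, 25L)
  ff <- vol3d(array(vals, d))
  voi <- mask3d(array(TRUE, d))
  thr <- mt_threshold(ff, voi)
  expect_false(thr$unimodal)
  # oracle: dense numeric minimisation of the mixture density between the
  # modes
  grid <- seq(70, 800, by = 0.1)
  dens <- 0.5 * stats::dnorm(grid, 70, 30) + 0.5 * stats::dnorm(grid, 800, 30)
  oracle <- grid[which.min(dens)]
  expect_lte(abs(thr$threshold - oracle), 2 * 10)
})

test_that("mt_threshold lies strictly between two delta populations and is
           invariant to count scaling", {
  d <- c(30L, 30L, 10L)
  vals <- rep(c(50, 800), length.out = prod(d))
  ff <- vol3d(array(vals, d))
  voi <- mask3d(array(TRUE, d))
  thr <- mt_threshold(ff, voi)
  expect_gt(thr$threshold, 50)
  expect_lt(thr$threshold, 800)

  # scaling all counts by 10 (here: replicating the VOI content) keeps the
  # argmin bin
  d10 <- c(30L, 30L, 100L)
  ff10 <- vol3d(array(rep(vals, 10L), d10))
  thr10 <- mt_threshold(ff10, mask3d(array(TRUE, d10)))
  expect_equal(thr10$threshold, thr$threshold)
})

test_that("a unimodal FF histogram flags failure and suggests 500", {
  d <- c(20L, 20L, 10L)
  ff <- vol3d(array(stats::rnorm(prod(d), 300, 25), d))
  expect_warning(thr <- mt_threshold(ff, mask3d(array(TRUE, d))),
                 "fallback")
  expect_true(thr$unimodal)
  expect_equal(thr$threshold, 500)
})

test_that("ff_mt converts the scanner scale: 1000 -> 100%, 0 -> 0%, mean of
           40/100 -> 7%", {
  d <- c(10L, 10L, 2L)
  voi <- mask3d(array(TRUE, d))
  expect_equal(ff_mt(vol3d(array(1000, d)), voi), 100)
  expect_equal(ff_mt(vol3d(array(0, d)), voi), 0)
  half <- array(rep(c(40, 100), each = prod(d) / 2), d)
  expect_equal(ff_mt(vol3d(half), voi), 7)
  expect_error(ff_mt(vol3d(half), mask3d(array(FALSE, d))), "empty")
})

test_that("FF_MT is monotone in the MT threshold", {
  s <- small_stages()
  ph <- s$ph
  voi <- like_mask(ph$truth$if_region$values & !ph$truth$femur$values,
                   ph$t1w)
  ffv <- resample(ph$ff, ph$truth$rigid_offset, target = ph$t1w)
  prev <- -Inf
  for (thr in c(150, 300, 600, 900)) {
    mt <- like_mask(voi$values & ffv$values < thr, ph$t1w)
    val <- ff_mt(ffv, mt)
    expect_gte(val, prev)
    prev <- val
  }
})
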