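test_that("a linear intensity ramp has zero Hessian eigenvalues in the
           interior", {
  d <- c(30, 30, 8)
  ramp <- array(rep(seq_len(d[1L]), d[2L] * d[3L]) * 5, d)
  vol <- vol3d(ramp, spacing = c(0.5, 0.5, 0.5))
  ef <- hessian_eigen(vol, 1.0)
  core <- ef$l3[10:20, 10:20, 4:5]
  expect_lt(max(abs(core)), 1e-8)
})

test_that("Hessian eigenvalues at a dark Gaussian-sheet centre match the
           dense finite-difference oracle within 5%", {
  d <- c(81, 41, 21)
  sp <- c(0.5, 0.5, 0.5)
  w <- 1.5; a <- 100
  x <- (seq_len(d[1L]) - 41) * sp[1L]
  profile <- -a * exp(-x^2 / (2 * w^2)) + 200
  vol <- vol3d(array(rep(profile, d[2L] * d[3L]), d), spacing = sp)
  ef <- hessian_eigen(vol, sigma_mm = w)

  # oracle: 1D dense convolution + finite differences, times sigma^2
  oracle <- fd_hessian_xx(profile, w / sp[1L], sp[1L]) * w^2
  center_oracle <- oracle[41 - 1L]        # aligned index for x = 0
  got <- ef$l3[41, 21, 11]
  expect_lt(abs(got - center_oracle) / abs(center_oracle), 0.05)
  expect_lt(abs(ef$l1[41, 21, 11]), 0.05 * abs(got))
  expect_lt(abs(ef$l2[41, 21, 11]), 0.05 * abs(got))
  expect_gt(got, 0)   # dark sheet on bright background: positive curvature
})

test_that("rotating the sheet 30 degrees in-plane changes the principal
           eigenvalue by < 5%", {
  d <- c(81, 81, 9)
  sp <- c(0.5, 0.5, 0.5)
  w <- 1.5; a <- 100
  mk <- function(theta) {
    i <- (seq_len(d[1L]) - 41) * sp[1L]
    xy <- outer(i * cos(theta), i * sin(theta), "+")
    arr <- array(rep(-a * exp(-xy^2 / (2 * w^2)) + 200, d[3L]), d)
    vol3d(arr, spacing = sp)
  }
  e0 <- hessian_eigen(mk(0), w)$l3[41, 41, 5]
  e30 <- hessian_eigen(mk(pi / 6), w)$l3[41, 41, 5]
  expect_lt(abs(e30 - e0) / abs(e0), 0.05)
})

test_that("plate weights: high on the fascia sheet, low on a blob, zero on
           uniform regions and bright plates", {
  s <- small_stages()
  flv <- s$ph$truth$fascia$values & !s$me$values
  expect_gte(stats::median(s$weights$values[flv]), 0.9)

  # spherical dark blob with radius equal to the sheet thickness
  d <- c(41, 41, 21); sp <- c(0.5, 0.5, 0.5)
  i <- (seq_len(d[1L]) - 21) * sp[1L]
  r2 <- outer(outer(i^2, i^2, "+"), i[1:21 + 10]^2, "+")
  blob <- vol3d(200 - 100 * exp(-r2 / (2 * 1.5^2)), spacing = sp)
  allm <- like_mask(array(TRUE, d), blob)
  none <- like_mask(array(FALSE, d), blob)
  wb <- plate_weight(hessian_eigen(blob, 1.5), allm, none)
  expect_lt(wb$values[21, 21, 11],
            0.5 * stats::median(s$weights$values[flv]))

  # uniform region: S -> 0 suppresses everything
  flat <- vol3d(array(300, d), spacing = sp)
  wf <- plate_weight(hessian_eigen(flat, 1.5), allm, none, c = 10)
  expect_true(all(wf$values == 0))

  # bright plate (inverted contrast): l3 <= 0 polarity gate
  xs <- (seq_len(d[1L]) - 21) * sp[1L]
  bright <- vol3d(array(rep(100 * exp(-xs^2 / (2 * 1.5^2)) + 100,
                            d[2L] * d[3L]), d), spacing = sp)
  wbr <- plate_weight(hessian_eigen(bright, 1.5), allm, none)
  # centre band |x| < sqrt(2)*w has negative principal curvature
  expect_equal(max(wbr$values[18:24, , ]), 0)
})

test_that("weight map support is restricted to fibrous voxels outside ME
           and range is [0,1]", {
  s <- small_stages()
  support <- tissue_mask(s$lab, "fibrous")$values & !s$me$values
  expect_true(all(s$weights$values[!support] == 0))
  expect_true(all(s$weights$values >= 0 & s$weights$values <= 1))
})

test_that("weights are invariant under adding a constant to the image", {
  s <- small_stages()
  shifted <- like_volume(s$bc$volume$values + 500, s$bc$volume)
  w2 <- fascia_weights(shifted, tissue_mask(s$lab, "fibrous"), s$me)
  expect_equal(w2$values, s$weights$values, tolerance = 1e-9)
})

test_that("the FL surface encloses the truth IF region and respects
           ME subset IF subset thigh", {
  s <- small_stages()
  expect_gte(dice(s$fl$if_voi, s$ph$truth$if_region), 0.90)
  expect_gt(sum(s$fl$if_voi$values), sum(s$me$values))  # IF strictly > ME
  expect_true(all(s$me$values <= s$fl$if_voi$values))
  expect_true(all(s$fl$if_voi$values <= s$thigh$values))
  expect_false(s$fl$degenerate)
})

test_that("zero fascia evidence collapses IF onto ME with a warning flag", {
  s <- small_stages()
  zero <- s$weights
  zero$values[] <- 0
  expect_warning(fl0 <- fl_surface(s$me, zero, s$thigh), "degenerate|fascia")
  expect_true(fl0$degenerate)
  expect_identical(fl0$if_voi$values, s$me$values)
})

test_that("the saphenous decoy arc is bypassed: no decoy voxel lies on the
           IF boundary", {
  s <- small_stages()
  boundary <- fasciata:::slice_boundary(s$fl$if_voi$values)
  expect_equal(sum(boundary & s$ph$truth$decoy$values), 0)
})

test_that("per-slice IF boundaries are single simple closed contours", {
  s <- small_stages()
  for (k in c(1L, 6L, 12L)) {
    ct <- s$fl$contours[[k]]
    expect_gt(nrow(ct), 20L)
    expect_equal(anyDuplicated(ct), 0L)
    # the traced contour covers the slice boundary voxels
    bd <- which(fasciata:::slice_boundary(
      s$fl$if_voi$values[, , k, drop = FALSE])[, , 1L], arr.ind = TRUE) - 1L
    expect_lte(abs(nrow(ct) - nrow(bd)) / nrow(bd), 0.35)
  }
})

test_that("sigma below the in-plane spacing is rejected", {
  s <- small_stages()
  expect_error(hessian_eigen(s$bc$volume, 0.2), "spacing")
})
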