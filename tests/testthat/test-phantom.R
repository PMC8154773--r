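test_that("phantom generation is seed-deterministic and bit-stable", {
  a <- make_phantom(small_spec())
  b <- make_phantom(small_spec())
  expect_identical(a$t1w$values, b$t1w$values)
  expect_identical(a$ff$values, b$ff$values)
  expect_identical(a$truth$labels$values, b$truth$labels$values)
})

test_that("a lean phantom (no perimuscular fat, no streaks) has zero IMAT", {
  ph <- make_phantom(small_spec(perimuscular_fat_fraction = 0,
                                intramuscular_streak_count = 0L))
  expect_equal(ph$truth$imat_fl_cm3, 0)
  expect_equal(ph$truth$imat_me_cm3, 0)
  expect_equal(sum(ph$truth$perimuscular$values), 0)
})

test_that("IMAT_FL - IMAT_ME equals the perimuscular voxel volume (oracle:
           brute-force mask count)", {
  ph <- make_phantom(small_spec(perimuscular_fat_fraction = 0.3))
  voxvol <- prod(ph$t1w$spacing)
  oracle <- sum(ph$truth$perimuscular$values) * voxvol / 1000
  expect_equal(ph$truth$imat_fl_cm3 - ph$truth$imat_me_cm3, oracle)
  expect_gt(oracle, 0)
})

test_that("truth masks are mutually consistent", {
  ph <- small_phantom()
  tr <- ph$truth
  expect_true(all(tr$fascia$values <= tr$thigh$values))
  expect_equal(sum(tr$if_region$values & tr$sat$values), 0)
  expect_true(all(tr$me$values <= tr$if_region$values))
  expect_true(all(tr$femur$values <= tr$me$values))
  expect_gte(tr$imat_fl_cm3, tr$imat_me_cm3)
})

test_that("IMAT_FL >= IMAT_ME across specs, equality iff no perimuscular fat", {
  for (f in c(0, 0.1, 0.25, 0.35)) {
    ph <- make_phantom(small_spec(perimuscular_fat_fraction = f,
                                  rng_seed = 10L + round(100 * f)))
    if (f == 0)
      expect_equal(ph$truth$imat_fl_cm3, ph$truth$imat_me_cm3)
    else
      expect_gt(ph$truth$imat_fl_cm3, ph$truth$imat_me_cm3)
  }
})

test_that("noiseless unbiased phantom intensities are exactly the class
           means", {
  ph <- make_phantom(small_spec(noise_sd = 0, bias_coeffs = NULL))
  vals <- sort(unique(as.numeric(ph$t1w$values)))
  expect_true(all(vals %in% unname(small_spec()$class_means)))
})

test_that("resampling the FF volume back with the inverse offset recovers
           the unshifted FF field within interpolation tolerance", {
  ph <- make_phantom(small_spec(ff_noise_sd = 0))
  ph0 <- make_phantom(small_spec(ff_noise_sd = 0,
                                 rigid_offset = rigid3d()))
  # sampling the shifted FF at T(x) recovers the unshifted field at x;
  # linear interpolation is exact away from tissue interfaces, so the
  # check runs on class-constant neighbourhoods (interpolation tolerance)
  aligned <- resample(ph$ff, ph$truth$rigid_offset, target = ph0$ff)
  v <- ph0$ff$values
  same <- array(TRUE, dim(v))
  for (sh in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(2, 0),
                  c(-2, 0), c(0, 2), c(0, -2)))
    same <- same & v == fasciata:::shift_array(
      fasciata:::shift_array(v, 1L, sh[1L]), 2L, sh[2L])
  same[, , c(1L, dim(v)[3L])] <- FALSE
  expect_gt(mean(same), 0.25)  # a good share of the grid is class interior
  err <- abs(aligned$values[same] - v[same])
  expect_lt(mean(err), 0.01 * 1000)
})

test_that("geometry that cannot fit the grid is rejected", {
  expect_error(phantom_spec(thigh_radius_mm = 80), "too large")
  expect_error(phantom_spec(perimuscular_fat_fraction = 1), "\\[0, 1\\)")
  expect_error(phantom_spec(class_means = c(background = 10, fibrous = 5,
                                            muscle = 400, AT = 800,
                                            marrow = 800, skin = 700)),
               "background < fibrous")
  expect_error(phantom_spec(femur_radius_mm = 25), "femur")
})

test_that("apply_bias: identity field, hand-computed ratio, and mean-1
           normalisation", {
  ph <- make_phantom(small_spec(noise_sd = 0, bias_coeffs = NULL))
  # constant (empty) polynomial -> field == 1 -> identity
  out <- apply_bias(ph$t1w, c(x = 0), mask = ph$truth$thigh)
  expect_equal(out$values, ph$t1w$values, tolerance = 1e-12)

  # linear field: the ratio between two voxels equals the hand-evaluated
  # exp(c * (x1 - x2)) in normalised coordinates
  cx <- 0.2
  out <- apply_bias(ph$t1w, c(x = cx))
  d <- dim(ph$t1w$values)
  xn <- seq(-1, 1, length.out = d[1L])
  i1 <- c(20L, 48L, 6L); i2 <- c(70L, 48L, 6L)
  expected_ratio <- exp(cx * xn[i1[1L]]) / exp(cx * xn[i2[1L]])
  got_ratio <- (out$values[i1[1], i1[2], i1[3]] /
                  ph$t1w$values[i1[1], i1[2], i1[3]]) /
    (out$values[i2[1], i2[2], i2[3]] / ph$t1w$values[i2[1], i2[2], i2[3]])
  expect_equal(got_ratio, expected_ratio, tolerance = 1e-10)

  # normalisation over the mask
  for (coeffs in list(c(x = 0.3, yy = -0.2), c(z = 0.5, xy = 0.1))) {
    field <- attr(apply_bias(ph$t1w, coeffs, mask = ph$truth$thigh),
                  "field")
    expect_equal(mean(field$values[ph$truth$thigh$values]), 1,
                 tolerance = 1e-6)
  }
})
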