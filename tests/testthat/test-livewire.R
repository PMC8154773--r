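test_that("A* path cost equals textbook Dijkstra on 50 random 20x20 grids", {
  set.seed(421)
  for (rep in 1:50) {
    cm <- matrix(runif(400), 20L, 20L)
    a <- c(sample(0:19, 1L), sample(0:19, 1L))
    b <- c(sample(0:19, 1L), sample(0:19, 1L))
    got <- shortest_path(cm, 0L, a, b)
    expect_equal(got$cost, dijkstra_grid(cm, a, b), tolerance = 1e-12)
  }
})

test_that("on a uniform grid the path cost equals the closed-form straight-
           line cost", {
  cm <- matrix(0.4, 25L, 25L)
  a <- c(3L, 4L); b <- c(15L, 10L)
  # 8-connected straight path: max(|dx|,|dy|) steps, min(|dx|,|dy|) are
  # diagonal
  dd <- abs(b - a)
  expected <- 0.4 * (min(dd) * sqrt(2) + (max(dd) - min(dd)))
  got <- shortest_path(cm, 0L, a, b)
  expect_equal(got$cost, expected, tolerance = 1e-12)
  expect_equal(nrow(got$path), max(dd) + 1L)
})

test_that("degenerate and invalid path queries behave as declared", {
  cm <- matrix(1, 10L, 10L)
  same <- shortest_path(cm, 0L, c(4L, 4L), c(4L, 4L))
  expect_equal(same$cost, 0)
  expect_equal(nrow(same$path), 1L)
  expect_error(shortest_path(cm, 0L, c(-1L, 0L), c(2L, 2L)), "outside")
  cm[, 5L] <- NA   # impassable wall across the slice
  expect_error(shortest_path(cm, 0L, c(1L, 1L), c(8L, 8L)), "unreachable")
})

test_that("cost map is structureless-1, bounded in [0,1], and cheap on the
           fascia", {
  flat <- vol3d(array(7, c(20, 20, 3)))
  cm <- cost_map(flat, NULL)
  expect_true(all(cm$values == 1))
  expect_error(cost_map(flat, NULL, w_edge = 0.7, w_fascia = 0.4),
               "must equal 1")

  s <- small_stages()
  cf <- cost_map(s$bc$volume, s$weights)
  expect_true(all(cf$values >= 0 & cf$values <= 1))
  # a voxel on the FL centreline is cheaper than voxels >= 3 voxels away
  # in the same slice row
  k <- 6L
  fl_sl <- s$ph$truth$fascia$values[, , k] & !s$me$values[, , k]
  pick <- which(fl_sl, arr.ind = TRUE)[10L, ]
  far <- c(pick[1L] + 6L, pick[2L])
  expect_lt(cf$values[pick[1L], pick[2L], k],
            cf$values[far[1L], far[2L], k])
})

test_that("seed propagation is stationary on identical slices, tracks a
           drifting valley, and defaults to 10 slices", {
  expect_equal(formals(propagate_seeds)$n_slices, 10L)

  # stationary: identical slices
  d <- c(30L, 30L, 12L)
  base <- matrix(runif(900, 0.5, 1), 30L)
  base[10L, 15L] <- 0.01
  cf <- structure(list(values = array(base, d), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)), class = "cost_field")
  seeds <- seed_set(0L, rbind(c(9L, 14L), c(12L, 14L)))
  out <- propagate_seeds(seeds, cf, n_slices = 10L, window = 1L)
  expect_length(out, 10L)
  for (ss in out) expect_equal(ss$points[1L, ], c(9L, 14L))

  # drifting valley: 1 voxel/slice, window 2 keeps the seed within
  # 1 voxel of the valley
  drift <- array(1, d)
  for (k in seq_len(d[3L])) drift[9L + k, , k] <- 0
  cfd <- structure(list(values = drift, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)), class = "cost_field")
  seeds <- seed_set(0L, rbind(c(9L, 10L), c(9L, 20L)), closed = TRUE)
  out <- propagate_seeds(seeds, cfd, n_slices = 10L, window = 2L)
  for (i in seq_along(out)) {
    valley_x <- 9L + out[[i]]$slice
    expect_lte(max(abs(out[[i]]$points[, 1L] - valley_x)), 1L)
  }
})

test_that("livewire contour through seeds on the phantom follows the fascia", {
  s <- small_stages()
  cf <- cost_map(s$bc$volume, s$weights)
  k <- 6L
  fl_sl <- s$ph$truth$fascia$values[, , k + 1L]
  pts <- which(fl_sl, arr.ind = TRUE) - 1L
  ang <- atan2(pts[, 2L] - mean(pts[, 2L]), pts[, 1L] - mean(pts[, 1L]))
  seeds <- seed_set(k, pts[order(ang)[round(seq(1, length(ang),
                                                length.out = 9))[-9]], ])
  ct <- livewire_contour(cf, seeds)
  # every contour vertex within 2 voxels of the true fascia sheet
  fl_d <- fasciata:::dilate_slices(array(fl_sl, c(dim(fl_sl), 1L)), 2L)
  hits <- fl_d[cbind(ct[, 1L] + 1L, ct[, 2L] + 1L, 1L)]
  expect_gte(mean(hits), 0.95)
})

test_that("apply_refinement is idempotent, boundary-inclusive, and local to
           the edited slice", {
  s <- small_stages()
  k <- 6L
  ct <- s$fl$contours[[k + 1L]]
  edited <- apply_refinement(s$fl$if_voi, ct, k)
  expect_identical(edited$values[, , k + 1L], s$fl$if_voi$values[, , k + 1L])
  expect_identical(edited$values[, , -(k + 1L)],
                   s$fl$if_voi$values[, , -(k + 1L)])

  # square of side 6: boundary-inclusive area 36 on an empty slice,
  # cross-checked by brute-force point-in-polygon over the slice
  m <- mask3d(array(FALSE, c(20L, 20L, 3L)))
  sq <- rbind(c(2, 2), c(7, 2), c(7, 7), c(2, 7))
  m2 <- apply_refinement(m, sq, 1L)
  expect_equal(sum(m2$values[, , 2L]), 36L)
  inside_brute <- outer(0:19, 0:19, function(x, y)
    x >= 2 & x <= 7 & y >= 2 & y <= 7)
  expect_identical(m2$values[, , 2L], inside_brute)
  expect_equal(sum(m2$values[, , c(1L, 3L)]), 0L)

  expect_error(apply_refinement(m, rbind(c(0, 0), c(5, 5), c(5, 0),
                                         c(0, 5)), 1L),
               "self-intersecting")
})
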