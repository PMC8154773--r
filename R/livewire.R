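#' Livewire cost field
#'
#' Combines image edges and fascia evidence into a per-voxel local cost in
#' [0, 1]: `cost = w_edge * (1 - G) + w_fascia * (1 - w)`, where `G` is the
#' in-plane gradient magnitude normalised to [0, 1] within each slice and
#' `w` the plate-likeness weight.  Strong edges and high fascia evidence
#' are cheap, so globally optimal paths follow the fascia.
#'
#' @param volume (bias-corrected) T1w [vol3d()].
#' @param weights a `weight_map` ([plate_weight()]); `NULL` for zero fascia
#'   evidence.
#' @param w_edge,w_fascia combination weights, must sum to 1.
#' @return object of class `cost_field`: `values` (3D array in [0,1]),
#'   `w_edge`, `w_fascia`, grid geometry.
#' @export
cost_map <- function(volume, weights = NULL, w_edge = 0.6, w_fascia = 0.4) {
  if (abs(w_edge + w_fascia - 1) > 1e-9)
    stop("w_edge + w_fascia must equal 1")
  if (w_edge < 0 || w_fascia < 0) stop("weights must be non-negative")
  d <- dim(volume$values)
  if (is.null(weights))
    weights <- like_volume(array(0, d), volume)
  stopifnot_compatible(volume, weights, "volume and weight map")
  g <- array(0, d)
  sp <- volume$spacing
  for (k in seq_len(d[3L])) {
    sl <- volume$values[, , k, drop = FALSE]
    gx <- deriv_axis(sl, 1L, sp[1L])
    gy <- deriv_axis(sl, 2L, sp[2L])
    gm <- sqrt(gx^2 + gy^2)
    mx <- max(gm)
    g[, , k] <- if (mx > 0) gm / mx else gm
  }
  cost <- w_edge * (1 - g) + w_fascia * (1 - weights$values)
  structure(list(values = cost, w_edge = w_edge, w_fascia = w_fascia,
                 spacing = volume$spacing, origin = volume$origin),
            class = "cost_field")
}

#' Minimum-cost path within a slice (livewire / A*)
#'
#' Finds the 8-connected in-plane path between two voxels minimising the
#' summed edge cost, where each step costs the mean of the two endpoint
#' local costs times the Euclidean step length (1 or sqrt(2) voxels).  The
#' A* heuristic is the Euclidean distance to the target times the minimum
#' local cost in the slice, which never overestimates the remaining cost,
#' so the returned path is exactly optimal (equal to Dijkstra).  Ties are
#' broken deterministically by lexicographic (column-major) voxel order.
#' Voxels with `NA` cost are impassable.
#'
#' @param cost a `cost_field` (or plain 2D matrix of local costs).
#' @param slice 0-based slice index (ignored when `cost` is a matrix).
#' @param a,b length-2 integer 0-based (x, y) voxel coordinates.
#' @return list with `path` (n-by-2 matrix of 0-based coordinates from `a`
#'   to `b`) and `cost` (total path cost; 0 when `a == b`).
#' @export
shortest_path <- function(cost, slice = 0L, a, b) {
  cm <- if (inherits(cost, "cost_field"))
    cost$values[, , slice + 1L] else cost
  d <- dim(cm)
  a <- as.integer(a); b <- as.integer(b)
  check_in_slice <- function(p, nm) {
    if (any(p < 0L) || p[1L] >= d[1L] || p[2L] >= d[2L])
      stop(sprintf("seed %s outside the slice", nm))
  }
  check_in_slice(a, "a"); check_in_slice(b, "b")
  lin <- function(p) 1L + p[1L] + d[1L] * p[2L]
  la <- lin(a); lb <- lin(b)
  if (is.na(cm[la]) || is.na(cm[lb]))
    stop("seed lies in a masked (impassable) region")
  if (la == lb)
    return(list(path = matrix(a, 1L, 2L), cost = 0))

  n <- length(cm)
  hmin <- suppressWarnings(min(cm, na.rm = TRUE))
  bx <- b[1L]; by <- b[2L]
  xs <- rep.int(0:(d[1L] - 1L), d[2L])
  ys <- rep(0:(d[2L] - 1L), each = d[1L])
  heur <- sqrt((xs - bx)^2 + (ys - by)^2) * hmin

  dist <- rep(Inf, n)
  prev <- integer(n)
  settled <- logical(n)
  dist[la] <- 0
  # binary heap ordered by (f, node index) for deterministic ties
  hk <- numeric(0); hn <- integer(0)
  less <- function(i, j) hk[i] < hk[j] ||
    (hk[i] == hk[j] && hn[i] < hn[j])
  push <- function(key, node) {
    hk[length(hk) + 1L] <<- key; hn[length(hn) + 1L] <<- node
    i <- length(hk)
    while (i > 1L) {
      p <- i %/% 2L
      if (less(i, p)) {
        tmp <- hk[i]; hk[i] <<- hk[p]; hk[p] <<- tmp
        tmp <- hn[i]; hn[i] <<- hn[p]; hn[p] <<- tmp
        i <- p
      } else break
    }
  }
  pop <- function() {
    top <- hn[1L]
    last <- length(hk)
    hk[1L] <<- hk[last]; hn[1L] <<- hn[last]
    hk <<- hk[-last]; hn <<- hn[-last]
    i <- 1L; m <- length(hk)
    repeat {
      l <- 2L * i; r <- l + 1L; s <- i
      if (l <= m && less(l, s)) s <- l
      if (r <= m && less(r, s)) s <- r
      if (s == i) break
      tmp <- hk[i]; hk[i] <<- hk[s]; hk[s] <<- tmp
      tmp <- hn[i]; hn[i] <<- hn[s]; hn[s] <<- tmp
      i <- s
    }
    top
  }

  off <- c(-1L, 1L, -d[1L], d[1L], -d[1L] - 1L, -d[1L] + 1L,
           d[1L] - 1L, d[1L] + 1L)
  step_len <- c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2))
  dx <- c(-1L, 1L, 0L, 0L, 0L, 0L, -1L, 1L)[c(1, 2, 3, 4, 5, 6, 7, 8)]
  push(heur[la], la)
  while (length(hn) > 0L) {
    u <- pop()
    if (settled[u]) next
    settled[u] <- TRUE
    if (u == lb) break
    ux <- (u - 1L) %% d[1L]
    cu <- cm[u]
    for (t in 1:8) {
      v <- u + off[t]
      if (v < 1L || v > n) next
      vx <- (v - 1L) %% d[1L]
      if (abs(vx - ux) > 1L) next            # row wrap
      if (settled[v]) next
      cv <- cm[v]
      if (is.na(cv)) next
      nd <- dist[u] + (cu + cv) / 2 * step_len[t]
      if (nd < dist[v] - 1e-15) {
        dist[v] <- nd
        prev[v] <- u
        push(nd + heur[v], v)
      }
    }
  }
  if (!settled[lb]) stop("target unreachable from source")
  path <- lb
  while (path[1L] != la) path <- c(prev[path[1L]], path)
  coords <- cbind((path - 1L) %% d[1L], (path - 1L) %/% d[1L])
  list(path = coords, cost = dist[lb])
}

#' Seed set for livewire refinement
#'
#' @param slice 0-based source slice index.
#' @param points n-by-2 matrix of 0-based (x, y) seed coordinates.
#' @param closed logical: seeds describe a closed loop (requires >= 2
#'   seeds).
#' @return object of class `seed_set`.
#' @export
seed_set <- function(slice, points, closed = TRUE) {
  points <- matrix(as.integer(points), ncol = 2L)
  if (closed && nrow(points) < 2L)
    stop("a closed-loop seed set needs at least 2 seeds")
  structure(list(slice = as.integer(slice), points = points,
                 closed = isTRUE(closed)),
            class = "seed_set")
}

#' Propagate seeds across slices
#'
#' Copies each seed to the next slice and snaps it to the minimum-cost
#' voxel within a `(2*window+1)^2` in-plane search window, repeating slice
#' by slice for `n_slices` slices (default 10).  Ties go to the
#' lexicographically smallest voxel.  If `mask` is given and the best
#' window voxel falls outside it, the seed is kept unsnapped and flagged
#' in the `snapped` attribute.
#'
#' @param seeds a [seed_set()] on the source slice.
#' @param cost a `cost_field`.
#' @param n_slices how many subsequent slices to propagate to.
#' @param window half-width of the snap window in voxels.
#' @param mask optional [mask3d()] restricting valid seed positions.
#' @return list of [seed_set()]s, one per target slice (source excluded),
#'   each carrying a logical attribute `snapped` per seed.
#' @export
propagate_seeds <- function(seeds, cost, n_slices = 10L, window = 3L,
                            mask = NULL) {
  if (n_slices < 1L) stop("n_slices must be >= 1")
  d <- dim(cost$values)
  out <- vector("list", 0L)
  pts <- seeds$points
  for (step in seq_len(n_slices)) {
    k <- seeds$slice + step
    if (k > d[3L] - 1L) break
    cm <- cost$values[, , k + 1L]
    snapped <- logical(nrow(pts))
    newpts <- pts
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      x0 <- max(0L, p[1L] - window); x1 <- min(d[1L] - 1L, p[1L] + window)
      y0 <- max(0L, p[2L] - window); y1 <- min(d[2L] - 1L, p[2L] + window)
      sub <- cm[(x0:x1) + 1L, (y0:y1) + 1L, drop = FALSE]
      j <- which.min(sub)          # column-major: lexicographic tie-break
      best <- c(x0 + (j - 1L) %% nrow(sub), y0 + (j - 1L) %/% nrow(sub))
      ok <- is.null(mask) || mask$values[best[1L] + 1L, best[2L] + 1L,
                                         k + 1L]
      if (ok) { newpts[i, ] <- best; snapped[i] <- TRUE }
    }
    ss <- seed_set(k, newpts, seeds$closed)
    attr(ss, "snapped") <- snapped
    out[[length(out) + 1L]] <- ss
    pts <- newpts
  }
  out
}

#' Trace a full livewire contour through a seed set
#'
#' Chains [shortest_path()] between consecutive seeds (and back to the
#' first seed for a closed loop) into one contour.
#' @param cost a `cost_field`.
#' @param seeds a [seed_set()].
#' @return n-by-2 matrix of 0-based contour coordinates.
#' @export
livewire_contour <- function(cost, seeds) {
  pts <- seeds$points
  n <- nrow(pts)
  idx <- if (seeds$closed) c(seq_len(n), 1L) else seq_len(n)
  out <- NULL
  for (i in seq_len(length(idx) - 1L)) {
    seg <- shortest_path(cost, seeds$slice, pts[idx[i], ], pts[idx[i + 1L], ])
    p <- seg$path
    if (!is.null(out)) p <- p[-1L, , drop = FALSE]
    out <- rbind(out, p)
  }
  if (seeds$closed && nrow(out) > 1L) out <- out[-nrow(out), , drop = FALSE]
  out
}

#' Apply a refined contour to the IF mask
#'
#' Replaces one slice of the intra-fascia mask by the filled polygon of a
#' closed contour (even-odd fill; boundary voxels included).  All other
#' slices are untouched.  Consecutive contour vertices further than one
#' voxel apart are connected by straight raster segments first.
#'
#' @param if_voi the intra-fascia [mask3d()].
#' @param contour n-by-2 matrix of 0-based (x, y) vertex coordinates
#'   describing a closed, non-self-intersecting polygon.
#' @param slice 0-based slice index to edit.
#' @return the edited [mask3d()].
#' @export
apply_refinement <- function(if_voi, contour, slice) {
  d <- dim(if_voi$values)
  if (slice < 0L || slice > d[3L] - 1L) stop("slice out of range")
  contour <- matrix(as.numeric(contour), ncol = 2L)
  if (nrow(contour) < 3L) stop("contour needs at least 3 vertices")
  if (polygon_self_intersects(contour))
    stop("contour is self-intersecting")
  filled <- fill_polygon(contour, d[1:2])
  out <- if_voi$values
  out[, , slice + 1L] <- filled
  mask3d(out, if_voi$spacing, if_voi$origin)
}

# Bresenham raster of the closed polygon outline.
raster_outline <- function(contour) {
  n <- nrow(contour)
  pts <- NULL
  for (i in seq_len(n)) {
    p <- round(contour[i, ]); q <- round(contour[i %% n + 1L, ])
    steps <- max(abs(q - p), 1)
    t <- seq(0, 1, length.out = steps + 1L)
    seg <- cbind(round(p[1L] + t * (q[1L] - p[1L])),
                 round(p[2L] + t * (q[2L] - p[2L])))
    pts <- rbind(pts, seg)
  }
  unique(pts)
}

# Even-odd polygon fill on a 0-based voxel grid; boundary included.
fill_polygon <- function(contour, d2) {
  inside <- matrix(FALSE, d2[1L], d2[2L])
  xs <- rep.int(0:(d2[1L] - 1L), d2[2L])
  ys <- rep(0:(d2[2L] - 1L), each = d2[1L])
  vx <- contour[, 1L]; vy <- contour[, 2L]
  n <- length(vx)
  cross <- logical(length(xs))
  j <- n
  for (i in seq_len(n)) {
    cond <- (vy[i] > ys) != (vy[j] > ys)
    if (any(cond)) {
      xint <- vx[i] + (ys[cond] - vy[i]) * (vx[j] - vx[i]) /
        (vy[j] - vy[i])
      flip <- xs[cond] < xint
      cross[cond][flip] <- !cross[cond][flip]
      # (assignment via which to keep vectorised semantics)
    }
    j <- i
  }
  inside[cbind(xs + 1L, ys + 1L)] <- cross
  bd <- raster_outline(contour)
  keep <- bd[, 1L] >= 0 & bd[, 1L] < d2[1L] & bd[, 2L] >= 0 &
    bd[, 2L] < d2[2L]
  inside[bd[keep, , drop = FALSE] + 1L] <- TRUE
  inside
}

polygon_self_intersects <- function(contour) {
  n <- nrow(contour)
  if (n < 4L) return(FALSE)
  seg <- cbind(contour, contour[c(2:n, 1L), , drop = FALSE])
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (segments_cross(seg[i, 1:2], seg[i, 3:4],
                         seg[j, 1:2], seg[j, 3:4])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  o <- function(a, b, c)
    sign((b[1L] - a[1L]) * (c[2L] - a[2L]) -
           (b[2L] - a[2L]) * (c[1L] - a[1L]))
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
}
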