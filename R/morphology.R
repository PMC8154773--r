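# Morphological helpers shared by the segmentation stages.
#
# Structuring elements are 2D in-plane disks applied slice by slice: with
# 3 mm slices against 0.5 mm in-plane voxels, 3D elements would smear
# structures across slices.  Connected components, in contrast, are genuine
# 3D (6-connected) because the fascia and muscle are 3D objects.

disk_brush <- function(radius) {
  if (radius < 1) return(matrix(1, 1L, 1L))
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# EBImage morphology replicates image borders; erosion must instead treat
# everything outside the slice as background, so the border frame of the
# result is cleared to the brush radius.
erode_slices <- function(arr, radius = 1) {
  if (radius < 1) return(arr)
  out <- EBImage::erode(arr * 1, disk_brush(radius)) > 0.5
  r <- as.integer(radius)
  d <- dim(out)
  out[c(seq_len(r), d[1L] - seq_len(r) + 1L), , ] <- FALSE
  out[, c(seq_len(r), d[2L] - seq_len(r) + 1L), ] <- FALSE
  out
}

dilate_slices <- function(arr, radius = 1) {
  if (radius < 1) return(arr)
  EBImage::dilate(arr * 1, disk_brush(radius)) > 0.5
}

close_slices <- function(arr, radius = 1) {
  if (radius < 1) return(arr)
  EBImage::closing(arr * 1, disk_brush(radius)) > 0.5
}

open_slices <- function(arr, radius = 1)
  dilate_slices(erode_slices(arr, radius), radius)

# Fill 2D holes independently in every slice.
fill_holes_slices <- function(arr) {
  d <- dim(arr)
  out <- arr
  for (k in seq_len(d[3L]))
    out[, , k] <- EBImage::fillHull(arr[, , k] * 1) > 0.5
  out
}

# 3D connected-component labelling (6-connectivity) via an adjacency graph.
# Returns an integer array, 0 = background, components numbered by
# decreasing voxel count (1 = largest).
label_components_3d <- function(arr) {
  d <- dim(arr)
  fg <- which(arr)
  out <- array(0L, d)
  if (length(fg) == 0L) return(out)
  rank <- integer(prod(d))
  rank[fg] <- seq_along(fg)
  edges <- NULL
  strides <- c(1L, d[1L], d[1L] * d[2L])
  coord <- arrayInd(fg, d)
  for (ax in 1:3) {
    ok <- coord[, ax] < d[ax]
    nb <- fg[ok] + strides[ax]
    keep <- arr[nb]
    if (any(keep))
      edges <- c(edges, rbind(rank[fg[ok][keep]], rank[nb[keep]]))
  }
  g <- igraph::make_graph(edges = if (is.null(edges)) integer(0) else edges,
                          n = length(fg), directed = FALSE)
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  remap <- integer(comp$no)
  remap[ord] <- seq_len(comp$no)
  out[fg] <- remap[comp$membership]
  out
}

largest_component_3d <- function(arr) {
  lab <- label_components_3d(arr)
  lab == 1L & arr
}

# Boundary voxels of a mask within each slice (8-connected interior removed).
slice_boundary <- function(arr) arr & !erode_slices(arr, 1L)
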