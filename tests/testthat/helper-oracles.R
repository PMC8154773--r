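# Independent oracle implementations used by several test files.

# Textbook O(V^2) Dijkstra on an 8-connected cost grid (edge cost = mean of
# endpoint costs x Euclidean step length).
dijkstra_grid <- function(cm, a, b) {
  d <- dim(cm); n <- prod(d)
  lin <- function(p) 1L + p[1L] + d[1L] * p[2L]
  dist <- rep(Inf, n); dist[lin(a)] <- 0
  done <- logical(n)
  nb <- expand.grid(dx = -1:1, dy = -1:1)
  nb <- nb[!(nb$dx == 0 & nb$dy == 0), ]
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u]) || done[lin(b)]) break
    done[u] <- TRUE
    ux <- (u - 1L) %% d[1L]; uy <- (u - 1L) %/% d[1L]
    for (t in seq_len(nrow(nb))) {
      vx <- ux + nb$dx[t]; vy <- uy + nb$dy[t]
      if (vx < 0 || vx >= d[1L] || vy < 0 || vy >= d[2L]) next
      v <- 1L + vx + d[1L] * vy
      w <- (cm[u] + cm[v]) / 2 * sqrt(nb$dx[t]^2 + nb$dy[t]^2)
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist[lin(b)]
}

# Dense 1D Gaussian smoothing (stats::convolve) + central finite
# differences: oracle for the scale-space Hessian along a sheet normal.
fd_hessian_xx <- function(profile, sigma_vox, dx_mm) {
  r <- ceiling(4 * sigma_vox)
  k <- dnorm(seq(-r, r), sd = sigma_vox); k <- k / sum(k)
  n <- length(profile)
  padded <- c(rep(profile[1L], r), profile, rep(profile[n], r))
  sm <- stats::convolve(padded, rev(k), type = "filter")
  d2 <- (sm[3:length(sm)] - 2 * sm[2:(length(sm) - 1)] +
           sm[1:(length(sm) - 2)]) / dx_mm^2
  d2[seq_len(n - 2L)]   # aligned with profile[2:(n-1)]
}
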