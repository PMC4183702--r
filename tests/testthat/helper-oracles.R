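# Independent brute-force oracles used to validate the compiled kernels.
# These deliberately share no code with the implementation under test.

# Length of `segment` inside an axis-aligned box [x0,x1] x [y0,y1]
# (Liang-Barsky clipping).
clip_length <- function(segment, x0, x1, y0, y1) {
  sx <- segment[1, 1]; sy <- segment[1, 2]
  dx <- segment[2, 1] - sx; dy <- segment[2, 2] - sy
  t0 <- 0; t1 <- 1
  p <- c(-dx, dx, -dy, dy)
  q <- c(sx - x0, x1 - sx, sy - y0, y1 - sy)
  for (k in 1:4) {
    if (p[k] == 0) { if (q[k] < 0) return(0) }
    else {
      r <- q[k] / p[k]
      if (p[k] < 0) { if (r > t1) return(0); if (r > t0) t0 <- r }
      else { if (r < t0) return(0); if (r < t1) t1 <- r }
    }
  }
  max(t1 - t0, 0) * sqrt(dx^2 + dy^2)
}

# Dense M x N system matrix built by clipping every ray against every pixel
# box individually (independent of the Siddon traversal).
dense_system_oracle <- function(geom, grid) {
  n <- grid$n; h <- grid$pixel_size
  half <- n * h / 2
  M <- geom$views * geom$bins
  D <- matrix(0, M, n * n)
  i <- 0
  for (v in seq_len(geom$views)) {
    for (b in seq_len(geom$bins)) {
      i <- i + 1
      seg <- ray_segment(geom, v, b, grid)
      for (r in seq_len(n)) {
        y1 <- half - (r - 1) * h; y0 <- y1 - h
        for (cc in seq_len(n)) {
          x0 <- -half + (cc - 1) * h; x1 <- x0 + h
          len <- clip_length(seg, x0, x1, y0, y1)
          if (len > 0) D[i, (r - 1) * n + cc] <- len
        }
      }
    }
  }
  D
}

# Loop-based SART sweep on a dense matrix, straight from the update formula.
naive_sart_sweep <- function(D, p, f, lambda, views, bins) {
  for (v in seq_len(views)) {
    rays <- (v - 1) * bins + seq_len(bins)
    num <- rep(0, length(f))
    for (i in rays) {
      rs <- sum(D[i, ])
      if (rs <= 0) next
      num <- num + D[i, ] * (p[i] - sum(D[i, ] * f)) / rs
    }
    cs <- colSums(D[rays, , drop = FALSE])
    upd <- cs > 0
    f[upd] <- f[upd] + lambda * num[upd] / cs[upd]
  }
  f
}

# Loop-based soft-threshold filtering step (pseudo-inverse of the WTD).
naive_stf_filter <- function(f, w, alpha) {
  nr <- nrow(f); nc <- ncol(f)
  out <- f
  off <- cbind(dr = c(0, 0, -1, 1, -1, -1, 1, 1),
               dc = c(-1, 1, 0, 0, -1, 1, -1, 1),
               wt = c(1, 1, 1, 1, alpha, alpha, alpha, alpha))
  sw <- function(x) sign(x) * max(abs(x) - w, 0)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      acc <- 0; wsum <- 0
      for (k in 1:8) {
        rr <- r + off[k, "dr"]; c2 <- cc + off[k, "dc"]
        if (rr < 1 || rr > nr || c2 < 1 || c2 > nc || off[k, "wt"] == 0) next
        g <- f[rr, c2] + sw(f[r, cc] - f[rr, c2])
        acc <- acc + off[k, "wt"] * g
        wsum <- wsum + off[k, "wt"]
      }
      out[r, cc] <- acc / wsum
    }
  }
  out
}

# Small fan-beam test setups used across files: physical field of view kept
# at the head-study scale so the source stays outside the grid.
tiny_setup <- function(n = 8, views = 2, bins = 5, pixel_size = 0.5,
                       aperture = 1.0, sad = 20) {
  grid <- image_grid(matrix(0, n, n), pixel_size)
  geom <- fan_beam_geometry(views = views, bins = bins,
                           bin_aperture = aperture, source_to_axis = sad)
  list(grid = grid, geom = geom, A = system_matrix(geom, grid))
}
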