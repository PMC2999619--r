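# Shared raster helpers: reflected padding and O(1)-per-pixel box
# filters via integral images.  All rasters are numeric matrices indexed
# [row, col] with origin at the top-left.

pad_reflect <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  if (r >= h || r >= w) stop("padding radius exceeds raster size", call. = FALSE)
  ri <- c(rev(seq_len(r) + 1L), seq_len(h), h - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(w), w - seq_len(r))
  m[ri, ci, drop = FALSE]
}

# Sum over a (2r+1) x (2r+1) window centred at each pixel, edges
# reflected.
box_sum <- function(m, r) {
  if (r == 0L) return(m)
  p <- pad_reflect(m, r)
  cs <- apply(p, 2L, cumsum)
  cs <- rbind(0, cs)
  v <- cs[seq_len(nrow(m)) + 2L * r + 1L, , drop = FALSE] -
       cs[seq_len(nrow(m)), , drop = FALSE]
  cs2 <- t(apply(v, 1L, cumsum))
  if (nrow(v) == 1L) cs2 <- matrix(cumsum(v[1L, ]), nrow = 1L)
  cs2 <- cbind(0, cs2)
  cs2[, seq_len(ncol(m)) + 2L * r + 1L, drop = FALSE] -
    cs2[, seq_len(ncol(m)), drop = FALSE]
}

box_mean <- function(m, r) box_sum(m, r) / (2 * r + 1)^2

box_sd <- function(m, r) {
  mu <- box_mean(m, r)
  v <- box_mean(m * m, r) - mu * mu
  v[v < 1e-12] <- 0 # exact zero for constant windows
  sqrt(v)
}

# Local Shannon entropy (bits) of the window histogram after quantizing
# values into `bins` equal-width levels on [lo, hi].
box_entropy <- function(m, r, bins = 8L, lo = 0, hi = 2) {
  q <- pmin(pmax(floor((m - lo) / (hi - lo) * bins), 0), bins - 1)
  ent <- matrix(0, nrow(m), ncol(m))
  for (b in seq_len(bins) - 1L) {
    p <- box_mean((q == b) * 1, r)
    nz <- p > 1e-12
    ent[nz] <- ent[nz] - p[nz] * log2(p[nz])
  }
  # exact zero for constant windows despite float round-off
  ent[ent < 1e-9] <- 0
  ent
}

# Filled ellipse rasterization restricted to a bounding box; returns
# integer index vector into the full raster (column-major).
ellipse_px <- function(cx, cy, rx, ry, h, w) {
  x0 <- max(1L, floor(cx - rx)); x1 <- min(w, ceiling(cx + rx))
  y0 <- max(1L, floor(cy - ry)); y1 <- min(h, ceiling(cy + ry))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  dx <- (xs - cx) / rx
  dy <- (ys - cy) / ry
  inside <- outer(dy^2, dx^2, `+`) <= 1
  iy <- rep(ys, times = length(xs))[as.vector(inside)]
  ix <- rep(xs, each = length(ys))[as.vector(inside)]
  (ix - 1L) * h + iy
}

# Smooth [0,1] noise field: uniform noise blurred twice with a box
# filter and rescaled.
smooth_noise <- function(h, w, r = 8L) {
  n <- matrix(runif(h * w), h, w)
  n <- box_mean(box_mean(n, r), r)
  rng <- range(n)
  if (diff(rng) < 1e-12) return(matrix(0.5, h, w))
  (n - rng[1]) / diff(rng)
}
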