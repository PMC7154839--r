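# Internal geometry / raster helpers shared across modules.
#
# Conventions (fixed once for the whole package):
#   * points are (x, y) in pixel units, x rightward, y downward, origin at the
#     top-left pixel center; a point (x, y) addresses matrix cell [y + 1, x + 1]
#   * frames are 0-based; temporal intervals are half-open [start, end)
#   * masks are logical H x W matrices, flow fields are H x W x 2 arrays with
#     channels (u, v) in px/frame

`%||%` <- function(a, b) if (is.null(a)) b else a

fr <- function(f) as.integer(f) + 1L  # 0-based frame -> list index

as_pts <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  stopifnot(ncol(p) == 2L)
  storage.mode(p) <- "double"
  p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- clamp(x, 0, w - 1); y <- clamp(y, 0, h - 1)
  x0 <- clamp(floor(x), 0, w - 2); y0 <- clamp(floor(y), 0, h - 2)
  dx <- x - x0; dy <- y - y0
  i <- y0 + 1; j <- x0 + 1
  v00 <- img[cbind(i, j)];     v01 <- img[cbind(i, j + 1)]
  v10 <- img[cbind(i + 1, j)]; v11 <- img[cbind(i + 1, j + 1)]
  (1 - dy) * ((1 - dx) * v00 + dx * v01) + dy * ((1 - dx) * v10 + dx * v11)
}

# Sample a flow field at continuous positions; returns n x 2 displacements.
bilinear_flow <- function(flow, pts) {
  pts <- as_pts(pts)
  cbind(bilinear_sample(flow[, , 1], pts[, 1], pts[, 2]),
        bilinear_sample(flow[, , 2], pts[, 1], pts[, 2]))
}

# Distance from points to segment [a, b]; also the arc-length parameter s
# (clamped to [0, 1]) and the signed perpendicular offset.
point_segment <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  len2 <- vx * vx + vy * vy
  if (len2 < 1e-12) {
    d <- sqrt((px - a[1])^2 + (py - a[2])^2)
    return(list(dist = d, s = rep(0, length(px)), off = d))
  }
  s <- clamp(((px - a[1]) * vx + (py - a[2]) * vy) / len2, 0, 1)
  cx <- a[1] + s * vx; cy <- a[2] + s * vy
  off <- ((px - a[1]) * vy - (py - a[2]) * vx) / sqrt(len2)  # signed
  list(dist = sqrt((px - cx)^2 + (py - cy)^2), s = s, off = off)
}

mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no bounding box")
  c(xmin = min(idx[, 2]) - 1, ymin = min(idx[, 1]) - 1,
    xmax = max(idx[, 2]) - 1, ymax = max(idx[, 1]) - 1)
}

bbox_diag <- function(mask) {
  b <- mask_bbox(mask)
  sqrt((b["xmax"] - b["xmin"])^2 + (b["ymax"] - b["ymin"])^2)[[1]]
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no centroid")
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
}

# Trajectory accessors. A trajectory is list(id, start, points) with `points`
# an m x 2 matrix covering frames start .. start + m - 1 (0-based).
traj_last <- function(tr) tr$start + nrow(tr$points) - 1L

traj_alive <- function(tr, from, to) tr$start <= from && traj_last(tr) >= to

# points of `tr` on frames from..to as a matrix
traj_window <- function(tr, from, to) {
  tr$points[(from - tr$start + 1L):(to - tr$start + 1L), , drop = FALSE]
}

# Per-frame displacement of `tr` at frame f (point(f+1) - point(f)).
traj_disp <- function(tr) {
  p <- tr$points
  p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
}

l2 <- function(m) sqrt(rowSums(m * m))
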