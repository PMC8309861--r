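# Rasterization and resampling primitives shared by the scene generator,
# the evaluation metrics and CAM upsampling. One rasterizer is used both to
# draw ground-truth masks and to score predictions, so no rasterizer bias
# can enter the IoU.

#' Rasterize a simple polygon onto a pixel grid
#'
#' Even-odd scanline fill evaluated at pixel centers: pixel (x, y) — x =
#' column, y = row, 0-based — is inside when a horizontal ray from the
#' center crosses an odd number of polygon edges to its left. Edges are
#' treated half-open in y, so vertices on a scanline are counted once. For
#' a span (a, b] of crossings the filled centers are ceiling(a) .. ceiling(b)-1,
#' which makes a vertical edge at x = k - 0.5 fill columns up to k - 1.
#'
#' @param poly numeric matrix (or data.frame) with columns x, y, one vertex
#'   per row, in order; the polygon is closed implicitly.
#' @param height,width output grid size in pixels.
#' @return integer matrix `height` x `width`, 1 inside, 0 outside.
#' @export
rasterize_polygon <- function(poly, height, width) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L)
    stop("poly must be an n x 2 matrix of vertices, n >= 3")
  if (!polygon_is_simple(poly))
    stop("polygon is self-intersecting")
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  out <- matrix(0L, height, width)
  for (row in seq_len(height) - 1L) {
    # half-open in y: edge contributes where min(y) <= row < max(y)
    lo <- pmin(y1, y2); hi <- pmax(y1, y2)
    sel <- lo <= row & row < hi
    if (!any(sel)) next
    xc <- x1[sel] + (row - y1[sel]) * (x2[sel] - x1[sel]) / (y2[sel] - y1[sel])
    xc <- sort(xc)
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      a <- ceiling(xc[k]); b <- ceiling(xc[k + 1L]) - 1L
      a <- max(a, 0L); b <- min(b, width - 1L)
      if (a <= b) out[row + 1L, (a:b) + 1L] <- 1L
    }
  }
  out
}

# Simple-polygon test: no two non-adjacent edges intersect. O(n^2);
# polygons here have a handful of vertices.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  seg_int <- function(i, j) {
    d <- function(ax, ay, bx, by, cx, cy)
      (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    d1 <- d(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j])
    d2 <- d(x1[i], y1[i], x2[i], y2[i], x2[j], y2[j])
    d3 <- d(x1[j], y1[j], x2[j], y2[j], x1[i], y1[i])
    d4 <- d(x1[j], y1[j], x2[j], y2[j], x2[i], y2[i])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n <= 3L) return(TRUE)
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent through closure
      if (seg_int(i, j)) return(FALSE)
    }
  }
  TRUE
}

# Linear-interpolation weight matrix mapping n_in samples to n_out, with
# pixel-center alignment: output center i maps to input coordinate
# (i + 0.5) * n_in / n_out - 0.5, clamped to the valid range. Rows sum to 1,
# so channelwise application preserves per-pixel sums across channels.
interp_matrix <- function(n_in, n_out) {
  s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  s <- clamp(s, 0, n_in - 1)
  i0 <- floor(s); f <- s - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  m <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  m[cbind(idx, i0 + 1)] <- m[cbind(idx, i0 + 1)] + (1 - f)
  m[cbind(idx, i1 + 1)] <- m[cbind(idx, i1 + 1)] + f
  m
}

#' Bilinear resampling of a matrix or H x W x C array
#'
#' Pixel-center aligned separable linear interpolation; exactly linear in
#' the input, so quantities that sum to one across channels still do after
#' resampling.
#'
#' @param x matrix or 3-d array (rows x cols x channels).
#' @param out_h,out_w output size in pixels.
#' @return object of the same kind as `x` with the new spatial size.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  d <- dim(x)
  R <- interp_matrix(d[1], out_h)
  C <- t(interp_matrix(d[2], out_w))
  if (length(d) == 2L) return(R %*% x %*% C)
  out <- array(0, c(out_h, out_w, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- R %*% x[, , k] %*% C
  out
}

#' Nearest-neighbour resampling
#'
#' Used to register label masks back to the original frame size without
#' inventing intermediate label values.
#'
#' @inheritParams resize_bilinear
#' @export
resize_nearest <- function(x, out_h, out_w) {
  d <- dim(x)
  ri <- pmin(floor((seq_len(out_h) - 0.5) * d[1] / out_h), d[1] - 1) + 1
  ci <- pmin(floor((seq_len(out_w) - 0.5) * d[2] / out_w), d[2] - 1) + 1
  if (length(d) == 2L) return(x[ri, ci, drop = FALSE])
  x[ri, ci, , drop = FALSE]
}
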