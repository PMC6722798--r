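# Polygon geometry primitives shared by the sampling and synthetic modules.
# Polygons are n x 2 matrices (columns x, y) of ring vertices; the closing
# edge is implicit. Coordinates follow the package convention: 0-based,
# origin top-left, x rightward, y downward.

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise rings in a y-down coordinate system is not
#' guaranteed; callers needing magnitude take \code{abs()}.
#'
#' @param poly numeric n x 2 matrix of ring vertices.
#' @return signed area in square pixels.
#' @keywords internal
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# TRUE when no two non-adjacent edges of the ring intersect (proper or
# improper). All O(n^2) edge pairs are tested in one vectorized sweep;
# adequate for hand-traced nucleus outlines.
isSimplePolygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  x <- poly[, 1]; y <- poly[, 2]
  nxt <- c(seq_len(n)[-1], 1L)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  adjacent <- (j == i + 1L) | (i == 1L & j == n)  # share a vertex
  i <- i[!adjacent]; j <- j[!adjacent]
  if (!length(i)) return(TRUE)
  ax <- x[i]; ay <- y[i]; bx <- x[nxt[i]]; by <- y[nxt[i]]
  cx <- x[j]; cy <- y[j]; dx <- x[nxt[j]]; dy <- y[nxt[j]]
  cross <- function(ox, oy, px, py, qx, qy)
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  d1 <- cross(cx, cy, dx, dy, ax, ay)
  d2 <- cross(cx, cy, dx, dy, bx, by)
  d3 <- cross(ax, ay, bx, by, cx, cy)
  d4 <- cross(ax, ay, bx, by, dx, dy)
  proper <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
            ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  if (any(proper)) return(FALSE)
  onSeg <- function(px, py, qx, qy, rx, ry)  # r collinear with pq: on it?
    pmin(px, qx) - 1e-12 <= rx & rx <= pmax(px, qx) + 1e-12 &
    pmin(py, qy) - 1e-12 <= ry & ry <= pmax(py, qy) + 1e-12
  touching <- (d1 == 0 & onSeg(cx, cy, dx, dy, ax, ay)) |
              (d2 == 0 & onSeg(cx, cy, dx, dy, bx, by)) |
              (d3 == 0 & onSeg(ax, ay, bx, by, cx, cy)) |
              (d4 == 0 & onSeg(ax, ay, bx, by, dx, dy))
  !any(touching)
}

#' Even-odd point-in-polygon test
#'
#' Ray-crossing (even-odd rule) membership test, vectorized over query
#' points. Points exactly on the boundary are resolved arbitrarily by the
#' crossing parity; use \code{pointOnPolygonBoundary} where boundary hits
#' must count.
#'
#' @param px,py numeric vectors of query coordinates.
#' @param poly numeric n x 2 ring.
#' @return logical vector, TRUE for interior points.
#' @keywords internal
pointInPolygon <- function(px, py, poly) {
  vx <- poly[, 1]; vy <- poly[, 2]
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < vx[i] + (vx[j] - vx[i]) * (py - vy[i]) /
         ifelse(denom == 0, 1, denom))
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# TRUE for points lying on a ring edge, within tolerance tol.
pointOnPolygonBoundary <- function(px, py, poly, tol = 1e-9) {
  vx <- poly[, 1]; vy <- poly[, 2]
  n <- length(vx)
  on <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    ex <- vx[i] - vx[j]; ey <- vy[i] - vy[j]
    len2 <- ex^2 + ey^2
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - vx[j]) * ex + (py - vy[j]) * ey) / len2))
    d2 <- (vx[j] + t * ex - px)^2 + (vy[j] + t * ey - py)^2
    on <- on | d2 <= tol^2
    j <- i
  }
  on
}

# 0-based (ix, iy) indices of pixels whose centers (ix+0.5, iy+0.5) fall
# inside the polygon (even-odd rule), restricted to an H x W raster.
# Returns a 2-column integer matrix (ix, iy); zero rows when none.
polygonPixelIndices <- function(poly, width, height) {
  x0 <- max(0L, as.integer(floor(min(poly[, 1]) - 0.5)))
  x1 <- min(width - 1L, as.integer(ceiling(max(poly[, 1]))))
  y0 <- max(0L, as.integer(floor(min(poly[, 2]) - 0.5)))
  y1 <- min(height - 1L, as.integer(ceiling(max(poly[, 2]))))
  if (x1 < x0 || y1 < y0)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("ix", "iy"))))
  ix <- rep(x0:x1, times = y1 - y0 + 1L)
  iy <- rep(y0:y1, each = x1 - x0 + 1L)
  keep <- pointInPolygon(ix + 0.5, iy + 0.5, poly)
  cbind(ix = ix[keep], iy = iy[keep])
}
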