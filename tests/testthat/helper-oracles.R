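# Independent geometric oracles and small fixture builders used across the
# suite. The point-membership oracle deliberately uses the winding-number
# algorithm, a different construction from the even-odd ray crossing used
# by the package, so grid-selection agreement is a genuine cross-check.

# Winding-number point-in-polygon: nonzero winding <=> inside (equivalent
# to even-odd for simple polygons).
windingNumberInside <- function(px, py, poly) {
  vx <- poly[, 1]; vy <- poly[, 2]
  n <- nrow(poly)
  wn <- 0L
  isLeft <- function(x0, y0, x1, y1, x2, y2)
    (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    if (vy[k] <= py) {
      if (vy[k2] > py && isLeft(vx[k], vy[k], vx[k2], vy[k2], px, py) > 0)
        wn <- wn + 1L
    } else {
      if (vy[k2] <= py && isLeft(vx[k], vy[k], vx[k2], vy[k2], px, py) < 0)
        wn <- wn - 1L
    }
  }
  wn != 0L
}

# Brute-force selection oracle: every (roi, grid point) pair.
bruteForceSelect <- function(grid, rois) {
  pts <- gridPoints(grid)
  hit <- vapply(roiPolygons(rois), function(poly) {
    any(vapply(seq_len(nrow(pts)), function(k)
      windingNumberInside(pts[k, 1], pts[k, 2], poly), logical(1)))
  }, logical(1))
  roiIds(rois)[hit]
}

# Regular-polygon approximation of a disc.
discPolygon <- function(cx, cy, r, nVertices = 20L) {
  t <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  cbind(x = cx + r * cos(t), y = cy + r * sin(t))
}

# Measurement rows without going through an image, for scoring tests.
fakeMeasurements <- function(ods, positive = NULL) {
  n <- length(ods)
  data.frame(roi_id = if (n) paste0("n", seq_len(n)) else character(0),
             field_id = rep("field_1", n),
             pixel_count = rep(100L, n), mean_od = ods,
             is_positive = if (is.null(positive)) rep(NA, n) else positive,
             stringsAsFactors = FALSE)
}
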