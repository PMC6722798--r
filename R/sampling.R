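# Stereological grid sampling: overlay a regular cross grid, keep the
# nuclei hit by at least one cross, and measure mean DAB OD inside each
# outline.

#' Construct an ROISet
#'
#' @param polygons list of numeric n x 2 matrices (columns x, y), one
#'   simple ring of >= 3 vertices per nucleus.
#' @param ids character vector of case-unique ROI labels; defaults to
#'   \code{"roi_1", "roi_2", ...}.
#' @param fieldIds character vector naming the source field of each ROI;
#'   a single value is recycled.
#' @return an [ROISet-class].
#' @examples
#' sq <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
#' roiSet(list(sq), ids = "n1", fieldIds = "f1")
#' @export
roiSet <- function(polygons, ids = NULL, fieldIds = "field_1") {
  if (is.null(ids)) ids <- paste0("roi_", seq_along(polygons))
  if (length(fieldIds) == 1L) fieldIds <- rep(fieldIds, length(polygons))
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("x", "y")
    p
  })
  new("ROISet", polygons = polygons, ids = as.character(ids),
      fieldIds = as.character(fieldIds))
}

#' @describeIn roiSet number of ROIs in the set.
#' @param x an ROISet.
#' @export
setMethod("length", "ROISet", function(x) length(x@polygons))

#' @rdname roiSet
#' @param object an ROISet.
#' @export
setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet: %d nucleus outline(s) across %d field(s)\n",
              length(object@polygons), length(unique(object@fieldIds))))
})

#' @describeIn roiSet subset an ROISet, preserving order.
#' @param i index vector (integer or logical).
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "ROISet", function(x, i, j, ..., drop = TRUE) {
  new("ROISet", polygons = x@polygons[i], ids = x@ids[i],
      fieldIds = x@fieldIds[i])
})

#' ROI identifiers
#' @param x an [ROISet-class].
#' @return character vector of ROI ids.
#' @export
roiIds <- function(x) x@ids

#' ROI source fields
#' @param x an [ROISet-class].
#' @return character vector of field ids, one per ROI.
#' @export
roiFieldIds <- function(x) x@fieldIds

#' ROI polygons
#' @param x an [ROISet-class].
#' @return list of n x 2 vertex matrices.
#' @export
roiPolygons <- function(x) x@polygons

#' Overlay the regular cross grid on a field
#'
#' Places \code{nx * ny} crosses at the centers of a uniform
#' \code{nx x ny} partition of the field:
#' \code{x_i = (i + 0.5) * width / nx}, \code{y_j = (j + 0.5) * height / ny}
#' for 0-based \code{i, j}. Cell-center placement keeps every cross strictly
#' inside the image. The 24 x 18 default reflects the grid used on 4:3
#' fields at 400x magnification.
#'
#' @param width,height image extent in pixels; must exceed nx and ny.
#' @param nx,ny crosses per row and column (defaults 24 and 18).
#' @return a [SamplingGrid-class].
#' @examples
#' g <- makeGrid(240, 180)
#' nrow(gridPoints(g))  # 432 crosses
#' @export
makeGrid <- function(width, height, nx = 24, ny = 18) {
  if (width <= 0 || height <= 0)
    stop("grid input error: image dimensions must be positive")
  if (nx < 1 || ny < 1)
    stop("grid input error: nx and ny must be at least 1")
  if (width <= nx || height <= ny)
    stop("grid input error: image must be larger than the grid (width > nx, height > ny)")
  xs <- (seq_len(nx) - 0.5) * width / nx
  ys <- (seq_len(ny) - 0.5) * height / ny
  pts <- cbind(x = rep(xs, times = ny), y = rep(ys, each = nx))
  new("SamplingGrid", nx = as.integer(nx), ny = as.integer(ny),
      width = as.numeric(width), height = as.numeric(height), points = pts)
}

#' @rdname makeGrid
#' @param object a SamplingGrid.
#' @export
setMethod("show", "SamplingGrid", function(object) {
  cat(sprintf("SamplingGrid: %d x %d crosses on a %g x %g field\n",
              object@nx, object@ny, object@width, object@height))
})

#' Grid cross coordinates
#' @param x a [SamplingGrid-class].
#' @return numeric (nx*ny) x 2 matrix of cross coordinates (x, y).
#' @export
gridPoints <- function(x) x@points

#' Select nuclei hit by grid crosses
#'
#' Keeps the ROIs containing at least one grid cross in their interior or
#' on their boundary. A nucleus hit by several crosses is kept once (the
#' grid samples nuclei, not hits); input order is preserved. An empty
#' selection is a valid result.
#'
#' @param grid a [SamplingGrid-class].
#' @param rois an [ROISet-class].
#' @return the selected subset of \code{rois}, an [ROISet-class].
#' @export
selectNuclei <- function(grid, rois) {
  stopifnot(is(grid, "SamplingGrid"), is(rois, "ROISet"))
  px <- grid@points[, 1]; py <- grid@points[, 2]
  hit <- vapply(rois@polygons, function(poly) {
    bb <- px >= min(poly[, 1]) - 1e-9 & px <= max(poly[, 1]) + 1e-9 &
          py >= min(poly[, 2]) - 1e-9 & py <= max(poly[, 2]) + 1e-9
    if (!any(bb)) return(FALSE)
    any(pointInPolygon(px[bb], py[bb], poly) |
        pointOnPolygonBoundary(px[bb], py[bb], poly))
  }, logical(1))
  rois[hit]
}

#' Measure mean DAB OD inside one nucleus outline
#'
#' Averages the DAB map over the pixels whose centers fall inside the
#' polygon (even-odd rule), mirroring the raster behavior of common ROI
#' managers. The positivity flag is left unset; classification is the
#' scoring step's job.
#'
#' @param dab numeric \code{H x W} matrix of DAB OD (e.g. [dabMap()]).
#' @param roi an [ROISet-class] of length 1, or a single polygon matrix.
#' @param roiId,fieldId labels recorded in the output when \code{roi} is a
#'   bare polygon.
#' @return one-row data.frame with columns \code{roi_id}, \code{field_id},
#'   \code{pixel_count}, \code{mean_od}, \code{is_positive} (NA).
#' @export
measureNucleus <- function(dab, roi, roiId = "roi_1", fieldId = "field_1") {
  if (is(roi, "ROISet")) {
    stopifnot(length(roi) == 1L)
    poly <- roi@polygons[[1]]
    roiId <- roi@ids[1]; fieldId <- roi@fieldIds[1]
  } else {
    poly <- as.matrix(roi)
  }
  h <- nrow(dab); w <- ncol(dab)
  if (min(poly[, 1]) >= w || max(poly[, 1]) <= 0 ||
      min(poly[, 2]) >= h || max(poly[, 2]) <= 0)
    stop(sprintf("measurement error: ROI '%s' lies entirely outside the image",
                 roiId))
  idx <- polygonPixelIndices(poly, width = w, height = h)
  if (nrow(idx) == 0L)
    stop(sprintf("measurement error: ROI '%s' contains no pixel centers",
                 roiId))
  vals <- dab[cbind(idx[, "iy"] + 1L, idx[, "ix"] + 1L)]
  data.frame(roi_id = roiId, field_id = fieldId,
             pixel_count = nrow(idx), mean_od = mean(vals),
             is_positive = NA, stringsAsFactors = FALSE)
}

#' Measure all nuclei of an ROISet
#'
#' @param dab numeric \code{H x W} DAB OD matrix.
#' @param rois an [ROISet-class].
#' @return data.frame with one row per ROI, as in [measureNucleus()].
#' @export
measureNuclei <- function(dab, rois) {
  stopifnot(is(rois, "ROISet"))
  if (length(rois) == 0L)
    return(data.frame(roi_id = character(0), field_id = character(0),
                      pixel_count = integer(0), mean_od = numeric(0),
                      is_positive = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_len(length(rois)), function(i)
    measureNucleus(dab, rois[i])))
}

#' Pool nucleus measurements across the fields of one case
#'
#' Concatenates per-field measurement tables without reweighting: every
#' nucleus contributes equally to the case no matter how many came from its
#' field. Scoring expects at least \code{minFields} fields per case (10 in
#' the reference protocol at 400x); fewer triggers a warning, not an error.
#'
#' @param perField list of measurement data.frames, one per field.
#' @param minFields minimum expected number of fields (default 10).
#' @return a single measurement data.frame.
#' @export
poolFields <- function(perField, minFields = 10) {
  if (length(perField) < minFields)
    warning(sprintf("only %d field(s) supplied; at least %d recommended per case",
                    length(perField), minFields))
  if (length(perField) == 0L)
    return(data.frame(roi_id = character(0), field_id = character(0),
                      pixel_count = integer(0), mean_od = numeric(0),
                      is_positive = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, c(perField, list(make.row.names = FALSE)))
}
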