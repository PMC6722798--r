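#' @import methods
NULL

#' RGBImage: an acquired brightfield field
#'
#' An 8-bit RGB photomicrograph together with its white reference, the
#' per-channel intensity of unstained ("almost white") background used to
#' calibrate optical density. Pixel values are stored as numerics in
#' \code{[0, 255]} in an \code{H x W x 3} array indexed
#' \code{[row (y), column (x), channel (R,G,B)]}.
#'
#' Coordinates used throughout the package are continuous, 0-based, with the
#' origin at the top-left image corner, x rightward and y downward; the pixel
#' with 0-based indices \code{(ix, iy)} covers the unit square
#' \code{[ix, ix+1) x [iy, iy+1)} and has its center at
#' \code{(ix + 0.5, iy + 0.5)}.
#'
#' @slot pixels numeric array, \code{H x W x 3}, values in \code{[0, 255]}.
#' @slot whiteRef numeric(3), per-channel white reference \code{I0}; must be
#'   positive. Default 255 on all channels, matching fixed acquisition
#'   settings rather than per-image normalization.
#'
#' @seealso [RGBImage()], [rgbToOD()], [readRGBImage()]
#' @export
setClass("RGBImage",
  representation(pixels = "array", whiteRef = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (length(dim(p)) != 3L || dim(p)[3] != 3L)
      return("'pixels' must be an H x W x 3 array")
    if (dim(p)[1] < 1L || dim(p)[2] < 1L)
      return("image must have H >= 1 and W >= 1")
    if (anyNA(p) || min(p) < 0 || max(p) > 255)
      return("pixel intensities must lie in [0, 255]")
    if (length(object@whiteRef) != 3L || anyNA(object@whiteRef) ||
        any(object@whiteRef <= 0))
      return("'whiteRef' must be 3 positive values")
    TRUE
  }
)

#' ODImage: per-channel optical densities
#'
#' Base-10 optical densities per RGB channel,
#' \code{OD = -log10(I / I0)}, so OD is 0 at the white reference, 1.0 when
#' 90\% of photons are absorbed and 2.0 when 99\% are absorbed.
#'
#' @slot od numeric array, \code{H x W x 3}, finite and non-negative.
#' @seealso [rgbToOD()], [deconvolveStains()]
#' @export
setClass("ODImage",
  representation(od = "array"),
  validity = function(object) {
    o <- object@od
    if (length(dim(o)) != 3L || dim(o)[3] != 3L)
      return("'od' must be an H x W x 3 array")
    if (anyNA(o) || any(!is.finite(o)))
      return("optical densities must be finite")
    if (min(o) < 0)
      return("optical densities must be non-negative")
    TRUE
  }
)

#' StainMatrix: unit optical-density vectors of the stains
#'
#' A 3 x 3 matrix whose rows are unit-length per-channel OD vectors for
#' hematoxylin, DAB and a residual completion (the normalized cross product
#' of the first two). Row-multiplication convention: a pixel with stain
#' concentrations \code{c} has \code{od = c \%*\% M}.
#'
#' @slot M numeric 3 x 3 matrix with rows named
#'   \code{hematoxylin, dab, residual}; each row has Euclidean norm 1 and the
#'   matrix is invertible.
#' @seealso [stainMatrix()], [hdabStainMatrix()], [deconvolveStains()]
#' @export
setClass("StainMatrix",
  representation(M = "matrix"),
  validity = function(object) {
    M <- object@M
    if (!is.numeric(M) || !identical(dim(M), c(3L, 3L)))
      return("'M' must be a numeric 3 x 3 matrix")
    if (anyNA(M)) return("stain matrix must be finite")
    norms <- sqrt(rowSums(M^2))
    if (any(abs(norms - 1) > 1e-9))
      return("each stain vector must have unit Euclidean norm")
    if (abs(det(M)) < 1e-12)
      return("stain matrix is singular: stain vectors are collinear")
    TRUE
  }
)

#' StainMaps: per-stain concentration images
#'
#' Per-pixel stain contributions after color deconvolution, in OD units
#' ("concentration-like": the amount of each stain's unit OD vector present
#' at the pixel). The hematoxylin and DAB maps are clamped at zero;
#' unmixing noise is absorbed by the residual channel.
#'
#' @slot hematoxylin numeric \code{H x W} matrix, >= 0.
#' @slot dab numeric \code{H x W} matrix, >= 0.
#' @slot residual numeric \code{H x W} matrix (may be negative).
#' @seealso [deconvolveStains()], [reconstructRGB()]
#' @export
setClass("StainMaps",
  representation(hematoxylin = "matrix", dab = "matrix",
                 residual = "matrix"),
  validity = function(object) {
    d <- dim(object@hematoxylin)
    if (!identical(d, dim(object@dab)) || !identical(d, dim(object@residual)))
      return("all stain maps must share the same dimensions")
    if (min(object@dab) < 0 || min(object@hematoxylin) < 0)
      return("hematoxylin and DAB maps must be non-negative")
    TRUE
  }
)

#' SamplingGrid: the regular cross overlay
#'
#' A lattice of nx x ny regularly spaced crosses used for unbiased,
#' stereological selection of nuclei: only nuclei containing a cross are
#' measured. Crosses sit at the centers of a uniform nx x ny partition of
#' the field, so none falls on the image border.
#'
#' @slot nx integer, columns of crosses (default 24).
#' @slot ny integer, rows of crosses (default 18).
#' @slot width,height numeric, image extent in pixels.
#' @slot points numeric matrix (nx*ny) x 2, columns \code{x}, \code{y}, in
#'   0-based pixel coordinates (x rightward, y downward).
#' @seealso [makeGrid()], [selectNuclei()]
#' @export
setClass("SamplingGrid",
  representation(nx = "integer", ny = "integer",
                 width = "numeric", height = "numeric", points = "matrix"),
  validity = function(object) {
    if (object@nx < 1L || object@ny < 1L)
      return("grid must have nx >= 1 and ny >= 1")
    if (nrow(object@points) != object@nx * object@ny)
      return("grid must contain exactly nx * ny points")
    if (ncol(object@points) != 2L)
      return("'points' must have columns x and y")
    p <- object@points
    if (any(p[, 1] < 0) || any(p[, 1] > object@width) ||
        any(p[, 2] < 0) || any(p[, 2] > object@height))
      return("all grid points must lie inside the image bounds")
    TRUE
  }
)

#' ROISet: polygonal nucleus outlines
#'
#' An ordered collection of nucleus outlines (regions of interest) traced on
#' one or more fields of a case. Each polygon is a closed, simple
#' (non-self-intersecting) ring of at least 3 vertices with positive area,
#' in 0-based pixel coordinates.
#'
#' @slot polygons list of numeric n x 2 matrices (columns x, y), one ring
#'   per nucleus; the closing edge from last to first vertex is implicit.
#' @slot ids character, case-unique ROI labels.
#' @slot fieldIds character, identifier of the source field per ROI.
#' @seealso [roiSet()], [readROIs()], [selectNuclei()], [measureNucleus()]
#' @export
setClass("ROISet",
  representation(polygons = "list", ids = "character", fieldIds = "character"),
  validity = function(object) {
    n <- length(object@polygons)
    if (length(object@ids) != n || length(object@fieldIds) != n)
      return("'ids' and 'fieldIds' must match the number of polygons")
    if (anyDuplicated(object@ids))
      return(sprintf("duplicate ROI id(s): %s",
                     paste(unique(object@ids[duplicated(object@ids)]),
                           collapse = ", ")))
    for (i in seq_len(n)) {
      poly <- object@polygons[[i]]
      if (!is.matrix(poly) || ncol(poly) != 2L || !is.numeric(poly))
        return(sprintf("ROI '%s': polygon must be a numeric n x 2 matrix",
                       object@ids[i]))
      if (nrow(poly) < 3L)
        return(sprintf("ROI '%s': polygon needs at least 3 vertices",
                       object@ids[i]))
      if (anyNA(poly))
        return(sprintf("ROI '%s': polygon has missing vertices",
                       object@ids[i]))
      if (!isSimplePolygon(poly))
        return(sprintf("ROI '%s': polygon is self-intersecting",
                       object@ids[i]))
      if (abs(polygonArea(poly)) <= 0)
        return(sprintf("ROI '%s': polygon has zero area", object@ids[i]))
    }
    TRUE
  }
)

#' PositivityRule: the nuclear positivity cutoff
#'
#' A nucleus is called ER-positive when its mean DAB OD strictly exceeds
#' \code{threshold}; at exactly the threshold it is negative, matching the
#' convention that OD values of 0.1 and less belong to negative nuclei.
#' \code{detectionFloor} is a separate, lower cutoff marking where DAB is
#' considered detectable at all; set \code{threshold = detectionFloor} to
#' count any detectable DAB as positive (the reading under which faint
#' discordant cases surface).
#'
#' @slot threshold numeric, OD cutoff for positivity (default 0.1).
#' @slot detectionFloor numeric, OD above which DAB is detectable
#'   (default 0); must satisfy \code{0 <= detectionFloor <= threshold <= 1}.
#' @seealso [positivityRule()], [classifyPositive()], [scoreCase()]
#' @export
setClass("PositivityRule",
  representation(threshold = "numeric", detectionFloor = "numeric"),
  validity = function(object) {
    t <- object@threshold; f <- object@detectionFloor
    if (length(t) != 1L || length(f) != 1L || anyNA(c(t, f)))
      return("'threshold' and 'detectionFloor' must be single numbers")
    if (!(f >= 0 && f <= t && t <= 1))
      return("must satisfy 0 <= detectionFloor <= threshold <= 1")
    TRUE
  }
)

#' CaseScore: the per-case quantitative result
#'
#' The pooled, per-case outcome of the quantitative pipeline: percent of
#' measured nuclei called positive, mean nuclear DAB OD over all measured
#' nuclei, the quantitative ER score
#' \code{(percentPositive + 100 * meanIntensity) / 20}, its
#' Allred-compatible integer triple, and the discordance flag (proportion
#' score >= 3 with intensity score 0 -- a case with many faintly stained
#' positive nuclei, conventionally considered hypothetical).
#'
#' @slot caseId character, case label.
#' @slot nNuclei integer, number of measured nuclei (NA when scored from a
#'   summary rather than raw measurements).
#' @slot percentPositive numeric in \code{[0, 100]}.
#' @slot meanIntensity numeric, mean DAB OD over all measured nuclei.
#' @slot quantitativeScore numeric in \code{[0, 10]} for OD <= 1.
#' @slot qProportion integer 0-5, Allred proportion score of
#'   \code{percentPositive}.
#' @slot qIntensity integer 0-3, Allred intensity score of
#'   \code{meanIntensity}.
#' @slot qTotal integer 0-8, \code{qProportion + qIntensity}.
#' @slot discordant logical, \code{qProportion >= 3 && qIntensity == 0}.
#' @seealso [scoreCase()], [scoreFromSummary()]
#' @export
setClass("CaseScore",
  representation(caseId = "character", nNuclei = "integer",
                 percentPositive = "numeric", meanIntensity = "numeric",
                 quantitativeScore = "numeric",
                 qProportion = "integer", qIntensity = "integer",
                 qTotal = "integer", discordant = "logical"),
  validity = function(object) {
    if (object@percentPositive < 0 || object@percentPositive > 100)
      return("'percentPositive' must lie in [0, 100]")
    if (object@meanIntensity < 0)
      return("'meanIntensity' must be non-negative")
    expected <- (object@percentPositive + 100 * object@meanIntensity) / 20
    if (abs(object@quantitativeScore - expected) > 1e-9)
      return("'quantitativeScore' must equal (percent + 100*meanOD)/20")
    if (object@qTotal != object@qProportion + object@qIntensity)
      return("'qTotal' must equal qProportion + qIntensity")
    if (object@qProportion < 0L || object@qProportion > 5L)
      return("'qProportion' must be an integer 0-5")
    if (object@qIntensity < 0L || object@qIntensity > 3L)
      return("'qIntensity' must be an integer 0-3")
    TRUE
  }
)
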