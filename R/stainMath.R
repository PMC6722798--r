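# Beer-Lambert optical-density transform and H-DAB color deconvolution.
#
# Transmitted intensity I relates to stain amount through
# I = I0 * 10^(-OD); per-pixel OD is additive across stains, so unmixing is
# a linear solve against a matrix of unit stain vectors.

# Intensity floor: a zero count is treated as 1 count out of 255 of the
# white reference, capping OD near 2.4 and keeping the transform finite
# while preserving the working OD range of [0, 2].
.OD_EPS_FRACTION <- 1 / 255

#' Construct an RGBImage
#'
#' @param pixels numeric \code{H x W x 3} array of 8-bit intensities
#'   (0-255), indexed \code{[y, x, channel]} with channels R, G, B.
#' @param whiteRef white reference \code{I0}: per-channel intensity of
#'   unstained background; a single number is recycled across channels.
#' @return an [RGBImage-class] object.
#' @examples
#' img <- RGBImage(array(255, dim = c(4, 4, 3)))
#' dim(img)
#' @export
RGBImage <- function(pixels, whiteRef = 255) {
  if (length(whiteRef) == 1L) whiteRef <- rep(whiteRef, 3L)
  if (any(whiteRef <= 0))
    stop("calibration error: white reference must be positive per channel")
  new("RGBImage", pixels = pixels, whiteRef = as.numeric(whiteRef))
}

#' @describeIn RGBImage height and width (pixels) of the image.
#' @param x an RGBImage.
#' @export
setMethod("dim", "RGBImage", function(x) dim(x@pixels)[1:2])

#' @rdname RGBImage
#' @param object an RGBImage.
#' @export
setMethod("show", "RGBImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RGBImage: %d x %d pixels, 8-bit RGB, I0 = (%s)\n",
              d[2], d[1], paste(format(object@whiteRef), collapse = ", ")))
})

#' Pixel intensities of an image
#' @param x an [RGBImage-class].
#' @return the \code{H x W x 3} intensity array.
#' @export
imagePixels <- function(x) x@pixels

#' White reference of an image
#' @param x an [RGBImage-class].
#' @return numeric(3) per-channel \code{I0}.
#' @export
whiteRef <- function(x) x@whiteRef

#' Optical-density transform of an RGB image
#'
#' Converts 8-bit intensities to base-10 optical densities per channel,
#' \code{OD_c = -log10(max(I_c, eps) / I0_c)} with
#' \code{eps = I0_c / 255}, so OD is zero at the white reference,
#' strictly decreasing in intensity, and capped near 2.4 for black pixels.
#' On this scale OD 1.0 means 90\% of photons absorbed and OD 2.0 means
#' 99\% absorbed.
#'
#' @param image an [RGBImage-class].
#' @return an [ODImage-class] of the same dimensions.
#' @examples
#' img <- RGBImage(array(25.5, dim = c(2, 2, 3)))  # 10% transmission
#' odValues(rgbToOD(img))[1, 1, ]                   # OD 1 on each channel
#' @export
rgbToOD <- function(image) {
  stopifnot(is(image, "RGBImage"))
  I0 <- image@whiteRef
  if (any(I0 <= 0))
    stop("calibration error: white reference must be positive per channel")
  od <- image@pixels
  for (ch in 1:3) {
    eps <- I0[ch] * .OD_EPS_FRACTION
    od[, , ch] <- -log10(pmax(image@pixels[, , ch], eps) / I0[ch])
  }
  od[od < 0] <- 0  # intensities above I0 (specular glare) read as blank
  new("ODImage", od = od)
}

#' @rdname ODImage
#' @param object an ODImage.
#' @export
setMethod("show", "ODImage", function(object) {
  d <- dim(object@od)
  cat(sprintf("ODImage: %d x %d pixels, OD range [%.3f, %.3f]\n",
              d[2], d[1], min(object@od), max(object@od)))
})

#' Optical densities of an ODImage
#' @param x an [ODImage-class].
#' @return the \code{H x W x 3} OD array.
#' @export
odValues <- function(x) x@od

#' Build a stain matrix from hematoxylin and DAB OD vectors
#'
#' Normalizes the two supplied stain vectors to unit length and completes
#' the basis with their normalized cross product as a residual channel,
#' yielding an invertible 3 x 3 unmixing matrix. The construction is
#' invariant to the scale of its inputs.
#'
#' @param hematoxylin,dab numeric(3) per-channel OD vectors (any positive
#'   scale); must be non-zero and not collinear.
#' @return a [StainMatrix-class].
#' @examples
#' m <- stainMatrix(c(1, 0, 0), c(0, 1, 0))
#' stainVectors(m)
#' @export
stainMatrix <- function(hematoxylin, dab) {
  h <- as.numeric(hematoxylin); d <- as.numeric(dab)
  if (length(h) != 3L || length(d) != 3L)
    stop("stain vectors must have 3 components (per RGB channel)")
  nh <- sqrt(sum(h^2)); nd <- sqrt(sum(d^2))
  if (nh == 0 || nd == 0)
    stop("degenerate stain matrix: stain vectors must be non-zero")
  h <- h / nh; d <- d / nd
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-9)
    stop("degenerate stain matrix: hematoxylin and DAB vectors are collinear")
  M <- rbind(hematoxylin = h, dab = d, residual = r / nr)
  colnames(M) <- c("R", "G", "B")
  new("StainMatrix", M = M)
}

#' Default H-DAB stain matrix
#'
#' The standard published H-DAB unmixing vectors,
#' hematoxylin (0.650, 0.704, 0.286) and DAB (0.269, 0.568, 0.778), the
#' defaults used by the widely deployed ImageJ color-deconvolution plugin.
#'
#' @return a [StainMatrix-class].
#' @export
hdabStainMatrix <- function() {
  stainMatrix(c(0.650, 0.704, 0.286), c(0.269, 0.568, 0.778))
}

#' @rdname StainMatrix
#' @param object a StainMatrix.
#' @export
setMethod("show", "StainMatrix", function(object) {
  cat("StainMatrix (rows: unit OD vectors per RGB channel)\n")
  print(round(object@M, 4))
})

#' Stain vectors of a StainMatrix
#' @param x a [StainMatrix-class].
#' @return the 3 x 3 matrix with rows hematoxylin, dab, residual.
#' @export
stainVectors <- function(x) x@M

#' Color deconvolution: unmix OD into per-stain maps
#'
#' Solves, at every pixel, \code{od = c \%*\% M} for the three stain
#' contributions \code{c}, i.e. \code{c = od \%*\% solve(M)}. Unmixing is
#' linear; negative hematoxylin and DAB contributions (unmixing noise) are
#' clamped to zero after the solve, the residual channel is returned
#' unclamped. The DAB map is in OD units and is the quantitative ER signal.
#'
#' @param od an [ODImage-class].
#' @param m a [StainMatrix-class] (default [hdabStainMatrix()]).
#' @return a [StainMaps-class].
#' @export
deconvolveStains <- function(od, m = hdabStainMatrix()) {
  stopifnot(is(od, "ODImage"), is(m, "StainMatrix"))
  d <- dim(od@od)
  odFlat <- matrix(od@od, nrow = d[1] * d[2], ncol = 3)
  conc <- odFlat %*% solve(m@M)
  toMap <- function(v, clamp) {
    if (clamp) v[v < 0] <- 0
    matrix(v, nrow = d[1], ncol = d[2])
  }
  new("StainMaps",
      hematoxylin = toMap(conc[, 1], TRUE),
      dab = toMap(conc[, 2], TRUE),
      residual = toMap(conc[, 3], FALSE))
}

#' @rdname StainMaps
#' @param object a StainMaps.
#' @export
setMethod("show", "StainMaps", function(object) {
  d <- dim(object@dab)
  cat(sprintf(paste0("StainMaps: %d x %d pixels; DAB OD range ",
                     "[%.3f, %.3f], hematoxylin [%.3f, %.3f]\n"),
              d[2], d[1], min(object@dab), max(object@dab),
              min(object@hematoxylin), max(object@hematoxylin)))
})

#' DAB map of a StainMaps object
#' @param x a [StainMaps-class].
#' @return numeric \code{H x W} matrix of DAB OD.
#' @export
dabMap <- function(x) x@dab

#' Hematoxylin map of a StainMaps object
#' @param x a [StainMaps-class].
#' @return numeric \code{H x W} matrix of hematoxylin OD.
#' @export
hematoxylinMap <- function(x) x@hematoxylin

#' Forward Beer-Lambert rendering of stain maps
#'
#' Inverse of the OD transform plus unmixing: composes the per-stain
#' concentration maps with the stain matrix and renders an 8-bit RGB image,
#' \code{I_c = I0_c * 10^(-sum_s conc_s * M[s, c])}, rounded to the nearest
#' integer and clipped to \code{[0, 255]}. Used by the synthetic-slide
#' generator and by round-trip verification of the deconvolution.
#'
#' @param maps a [StainMaps-class] with non-negative hematoxylin/DAB maps.
#' @param m a [StainMatrix-class].
#' @param whiteRef white reference \code{I0}, single number or numeric(3).
#' @return an [RGBImage-class].
#' @export
reconstructRGB <- function(maps, m = hdabStainMatrix(), whiteRef = 255) {
  stopifnot(is(maps, "StainMaps"), is(m, "StainMatrix"))
  if (length(whiteRef) == 1L) whiteRef <- rep(whiteRef, 3L)
  d <- dim(maps@dab)
  conc <- cbind(as.vector(maps@hematoxylin), as.vector(maps@dab),
                as.vector(maps@residual))
  od <- conc %*% m@M
  px <- array(0, dim = c(d[1], d[2], 3))
  for (ch in 1:3) {
    px[, , ch] <- matrix(
      pmin(255, pmax(0, round(whiteRef[ch] * 10^(-od[, ch])))),
      nrow = d[1])
  }
  RGBImage(px, whiteRef = whiteRef)
}

#' Construct StainMaps from matrices
#'
#' @param hematoxylin,dab numeric \code{H x W} matrices of per-stain OD
#'   (non-negative).
#' @param residual optional numeric \code{H x W} matrix; defaults to zero.
#' @return a [StainMaps-class].
#' @export
stainMaps <- function(hematoxylin, dab, residual = NULL) {
  if (is.null(residual))
    residual <- matrix(0, nrow = nrow(dab), ncol = ncol(dab))
  new("StainMaps", hematoxylin = hematoxylin, dab = dab,
      residual = residual)
}
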