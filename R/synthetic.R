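# Forward-model synthetic slide generator: elliptical DAB-stained nuclei on
# a pale hematoxylin background, rendered through the Beer-Lambert model
# with known per-nucleus stain concentrations, so every pipeline stage can
# be tested against ground truth without real slides.

# Derive a reproducible substream seed from the master seed. Named
# substreams (placement / stain levels / acquisition noise / observer) let
# stages vary independently while staying fully determined by the master
# seed. Kept below 2^31 - 1 and exactly representable in doubles.
deriveSeed <- function(master, stream, index = 0) {
  as.integer(((master %% 2147483647) * 69069 + stream * 7919 + index) %%
               2147483647)
}

#' Specification of one synthetic case
#'
#' Parameters of the generator, chosen to emulate the reference acquisition
#' conditions: fields of 360 x 270 px at 400x-like scale, at least 10
#' fields per case, nuclei drawn as ellipses with axes 8-20 px, DAB OD of
#' positive nuclei around 0.5 (clearly above the 0.1 cutoff) and negatives
#' at 0, nuclear hematoxylin 0.3 over a pale 0.05 background.
#'
#' @param nNuclei nuclei per field (default 50).
#' @param nFields fields per case (default 10).
#' @param truePositiveFraction fraction of nuclei that are ER-positive, in
#'   \code{[0, 1]} (default 0.4).
#' @param dabOdPositive numeric(2) mean and SD of DAB OD for positive
#'   nuclei (default \code{c(0.5, 0.1)}); draws are kept above the
#'   positivity threshold so ground-truth labels stay consistent.
#' @param dabOdNegative numeric(2) mean and SD for negative nuclei
#'   (default \code{c(0, 0)}); draws are clamped into
#'   \code{[0, threshold]}.
#' @param hematoxylinNucleus nuclear hematoxylin OD (default 0.3).
#' @param hematoxylinBackground background hematoxylin OD (default 0.05).
#' @param noiseSd additive Gaussian intensity noise, in 8-bit counts,
#'   applied before quantization (default 0).
#' @param positivityThreshold OD cutoff the ground-truth labels refer to
#'   (default 0.1).
#' @param width,height field size in pixels (defaults 360 x 270).
#' @param axisRange numeric(2) range of full ellipse axes in pixels
#'   (default \code{c(8, 20)}).
#' @param seed master seed; every random stage derives its substream from
#'   it, so a spec renders identically every time.
#' @return a validated list of class \code{"SyntheticCaseSpec"}.
#' @export
syntheticCaseSpec <- function(nNuclei = 50, nFields = 10,
                              truePositiveFraction = 0.4,
                              dabOdPositive = c(0.5, 0.1),
                              dabOdNegative = c(0, 0),
                              hematoxylinNucleus = 0.3,
                              hematoxylinBackground = 0.05,
                              noiseSd = 0, positivityThreshold = 0.1,
                              width = 360, height = 270,
                              axisRange = c(8, 20), seed = 1L) {
  spec <- list(nNuclei = as.integer(nNuclei), nFields = as.integer(nFields),
               truePositiveFraction = truePositiveFraction,
               dabOdPositive = dabOdPositive, dabOdNegative = dabOdNegative,
               hematoxylinNucleus = hematoxylinNucleus,
               hematoxylinBackground = hematoxylinBackground,
               noiseSd = noiseSd, positivityThreshold = positivityThreshold,
               width = as.integer(width), height = as.integer(height),
               axisRange = axisRange, seed = as.integer(seed))
  stopifnot(spec$nNuclei >= 1, spec$nFields >= 1,
            spec$truePositiveFraction >= 0, spec$truePositiveFraction <= 1,
            all(spec$dabOdPositive >= 0), all(spec$dabOdNegative >= 0),
            spec$hematoxylinNucleus >= 0, spec$hematoxylinBackground >= 0,
            spec$noiseSd >= 0, spec$width > 0, spec$height > 0,
            length(spec$axisRange) == 2, spec$axisRange[1] >= 2,
            spec$axisRange[2] >= spec$axisRange[1])
  class(spec) <- "SyntheticCaseSpec"
  spec
}

# Ellipse ring with jittered axes as a 28-vertex polygon.
ellipsePolygon <- function(cx, cy, a, b, theta, nVertices = 28L) {
  t <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  cbind(x = cx + x * cos(theta) - y * sin(theta),
        y = cy + x * sin(theta) + y * cos(theta))
}

#' Render one synthetic field
#'
#' Places non-overlapping elliptical nuclei at random positions, assigns
#' each a hematoxylin OD plus a DAB OD drawn from its class distribution
#' (exactly \code{round(truePositiveFraction * nNuclei)} nuclei per field
#' are positive), paints the background with pale hematoxylin only, and
#' renders the 8-bit image through the Beer-Lambert forward model with
#' optional Gaussian intensity noise. Deterministic for a fixed spec.
#'
#' @param spec a [syntheticCaseSpec()].
#' @param fieldIndex 1-based field number within the case; shifts the
#'   random substreams so fields differ while staying reproducible.
#' @param stainMat the [StainMatrix-class] used as forward model (default
#'   [hdabStainMatrix()]).
#' @return list with components \code{image} ([RGBImage-class]),
#'   \code{rois} ([ROISet-class] of the true outlines), \code{maps}
#'   (the noise-free ground-truth [StainMaps-class]) and \code{truth}
#'   (data.frame: roi_id, field_id, center/axes/rotation, dab_od,
#'   is_positive).
#' @export
renderField <- function(spec, fieldIndex = 1L,
                        stainMat = hdabStainMatrix()) {
  stopifnot(inherits(spec, "SyntheticCaseSpec"))
  w <- spec$width; h <- spec$height
  n <- spec$nNuclei
  aMin <- spec$axisRange[1] / 2; aMax <- spec$axisRange[2] / 2

  # -- placement substream: rejection-sample non-overlapping ellipses
  set.seed(deriveSeed(spec$seed, 1L, fieldIndex))
  centers <- matrix(numeric(0), ncol = 2)
  axes <- matrix(numeric(0), ncol = 2)
  rot <- numeric(0)
  attempts <- 0L; maxAttempts <- 400L * n
  while (nrow(centers) < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop("generation error: infeasible packing (too many nuclei for the field)")
    a <- stats::runif(1, aMin, aMax); b <- stats::runif(1, aMin, aMax)
    r <- max(a, b)
    cx <- stats::runif(1, r + 1, w - r - 1)
    cy <- stats::runif(1, r + 1, h - r - 1)
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
      if (any(d < r + pmax(axes[, 1], axes[, 2]) + 1)) next
    }
    centers <- rbind(centers, c(cx, cy))
    axes <- rbind(axes, c(a, b))
    rot <- c(rot, stats::runif(1, 0, pi))
  }

  # -- stain-level substream: class labels and per-nucleus ODs
  set.seed(deriveSeed(spec$seed, 2L, fieldIndex))
  nPos <- round(spec$truePositiveFraction * n)
  isPos <- sample(rep(c(TRUE, FALSE), c(nPos, n - nPos)))
  thr <- spec$positivityThreshold
  dabOd <- numeric(n)
  dabOd[isPos] <- pmax(
    stats::rnorm(nPos, spec$dabOdPositive[1], spec$dabOdPositive[2]),
    thr + 1e-6)
  dabOd[!isPos] <- pmin(pmax(
    stats::rnorm(n - nPos, spec$dabOdNegative[1], spec$dabOdNegative[2]),
    0), thr)

  # -- paint ground-truth concentration maps
  hMap <- matrix(spec$hematoxylinBackground, nrow = h, ncol = w)
  dMap <- matrix(0, nrow = h, ncol = w)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    polys[[i]] <- ellipsePolygon(centers[i, 1], centers[i, 2],
                                 axes[i, 1], axes[i, 2], rot[i])
    idx <- polygonPixelIndices(polys[[i]], width = w, height = h)
    lin <- cbind(idx[, "iy"] + 1L, idx[, "ix"] + 1L)
    hMap[lin] <- spec$hematoxylinNucleus
    dMap[lin] <- dabOd[i]
  }
  maps <- stainMaps(hMap, dMap)

  # -- render through the forward model, with acquisition noise
  intens <- .forwardIntensity(maps, stainMat, whiteRef = 255)
  if (spec$noiseSd > 0) {
    set.seed(deriveSeed(spec$seed, 3L, fieldIndex))
    intens <- intens + array(stats::rnorm(length(intens), 0, spec$noiseSd),
                             dim = dim(intens))
  }
  image <- RGBImage(array(pmin(255, pmax(0, round(intens))),
                          dim = dim(intens)), whiteRef = 255)

  fieldId <- sprintf("field_%02d", fieldIndex)
  rois <- roiSet(polys,
                 ids = sprintf("%s_n%03d", fieldId, seq_len(n)),
                 fieldIds = fieldId)
  truth <- data.frame(roi_id = rois@ids, field_id = fieldId,
                      cx = centers[, 1], cy = centers[, 2],
                      a = axes[, 1], b = axes[, 2], theta = rot,
                      hematoxylin_od = spec$hematoxylinNucleus,
                      dab_od = dabOd, is_positive = isPos,
                      stringsAsFactors = FALSE)
  list(image = image, rois = rois, maps = maps, truth = truth)
}

# Unrounded forward Beer-Lambert intensities (shared by reconstructRGB and
# the noisy renderer).
.forwardIntensity <- function(maps, m, whiteRef = 255) {
  if (length(whiteRef) == 1L) whiteRef <- rep(whiteRef, 3L)
  d <- dim(maps@dab)
  conc <- cbind(as.vector(maps@hematoxylin), as.vector(maps@dab),
                as.vector(maps@residual))
  od <- conc %*% m@M
  out <- array(0, dim = c(d[1], d[2], 3))
  for (ch in 1:3) out[, , ch] <- matrix(whiteRef[ch] * 10^(-od[, ch]),
                                        nrow = d[1])
  out
}

#' Run the full quantitative pipeline on one synthetic case
#'
#' Renders every field of the spec, then runs the measurement pipeline
#' exactly as it would run on acquired images: OD transform, H-DAB
#' deconvolution, grid selection of nuclei, per-nucleus mean DAB OD, field
#' pooling and case scoring.
#'
#' @param spec a [syntheticCaseSpec()].
#' @param rule a [PositivityRule-class].
#' @param grid a [SamplingGrid-class]; defaults to the 24 x 18 grid over
#'   the spec's field size.
#' @param caseId case label.
#' @param stainMat forward/unmixing [StainMatrix-class].
#' @return list with \code{score} ([CaseScore-class]),
#'   \code{measurements} (pooled data.frame), \code{truth} (per-nucleus
#'   ground truth with a \code{selected} flag) and \code{truthSelected}
#'   (ground-truth percent positive and mean OD among selected nuclei).
#' @export
scoreSyntheticCase <- function(spec, rule = positivityRule(),
                               grid = NULL, caseId = "case_1",
                               stainMat = hdabStainMatrix()) {
  stopifnot(inherits(spec, "SyntheticCaseSpec"))
  if (is.null(grid))
    grid <- makeGrid(spec$width, spec$height)
  perField <- vector("list", spec$nFields)
  truthAll <- vector("list", spec$nFields)
  for (f in seq_len(spec$nFields)) {
    fld <- renderField(spec, f, stainMat = stainMat)
    dab <- dabMap(deconvolveStains(rgbToOD(fld$image), stainMat))
    sel <- selectNuclei(grid, fld$rois)
    perField[[f]] <- measureNuclei(dab, sel)
    fld$truth$selected <- fld$truth$roi_id %in% roiIds(sel)
    truthAll[[f]] <- fld$truth
  }
  pooled <- suppressWarnings(poolFields(perField,
                                        minFields = spec$nFields))
  pooled <- classifyPositive(pooled, rule)
  truth <- do.call(rbind, truthAll)
  tSel <- truth[truth$selected, , drop = FALSE]
  list(score = scoreCase(pooled, rule, caseId = caseId),
       measurements = pooled, truth = truth,
       truthSelected = list(
         percent_positive = 100 * mean(tSel$is_positive),
         mean_od = mean(tSel$dab_od),
         n = nrow(tSel)))
}

#' Generate a synthetic cohort with ground truth and observer scores
#'
#' Draws one case specification per case (positive fraction uniform on
#' \code{[0, 1]}; DAB OD of positive nuclei increasing with the positive
#' fraction plus jitter, emulating the empirical coupling between
#' abundance and staining strength), renders and scores each case through
#' the full pipeline, and attaches a semi-quantitative "pathologist" score
#' derived from ground truth: the Allred proportion bins applied to the
#' true percent positive, and an intensity score from the true mean OD of
#' positive nuclei, perturbed by +/-1 with probability
#' \code{observerNoise}. Fully reproducible from the master seed.
#'
#' @param nCases number of cases (>= 1).
#' @param seed master seed.
#' @param nNuclei,nFields per-case generator size (defaults 50 and 10).
#' @param observerNoise probability that the synthetic pathologist's
#'   intensity score is off by one (default 0.1).
#' @param noiseSd acquisition noise in intensity counts (default 0).
#' @param width,height field size in pixels.
#' @param rule a [PositivityRule-class].
#' @return data.frame with one row per case: \code{case_id},
#'   \code{sq_proportion}, \code{sq_intensity}, \code{sq_total},
#'   \code{percent_positive}, \code{mean_intensity},
#'   \code{quantitative_score}, \code{q_proportion_score},
#'   \code{q_intensity_score}, \code{q_total}, \code{discordant}, plus
#'   ground-truth columns \code{true_percent_positive} and
#'   \code{true_mean_od}.
#' @export
generateCohort <- function(nCases, seed = 1L, nNuclei = 50, nFields = 10,
                           observerNoise = 0.1, noiseSd = 0,
                           width = 360, height = 270,
                           rule = positivityRule()) {
  stopifnot(nCases >= 1)
  rows <- vector("list", nCases)
  for (i in seq_len(nCases)) {
    spec <- .drawCohortCaseSpec(seed, i, nNuclei, nFields, noiseSd, rule)
    spec$width <- as.integer(width); spec$height <- as.integer(height)
    res <- scoreSyntheticCase(spec, rule,
                              caseId = sprintf("case_%03d", i))
    rows[[i]] <- .observerRow(res, res$truth, seed, i, observerNoise)
  }
  do.call(rbind, rows)
}
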