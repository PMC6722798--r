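# Case-level scoring: nuclear positivity at the OD cutoff, the quantitative
# ER score, and the Allred-compatible integer triple with discordance
# detection.

#' Construct a PositivityRule
#'
#' @param threshold OD cutoff for calling a nucleus positive; a nucleus is
#'   positive when mean DAB OD strictly exceeds it (default 0.1, the lowest
#'   10\% of the attainable OD <= 1 range).
#' @param detectionFloor OD above which DAB is considered detectable at all
#'   (default 0). Set \code{threshold = detectionFloor} to count every
#'   nucleus with detectable DAB as positive.
#' @return a [PositivityRule-class].
#' @export
positivityRule <- function(threshold = 0.1, detectionFloor = 0) {
  new("PositivityRule", threshold = as.numeric(threshold),
      detectionFloor = as.numeric(detectionFloor))
}

#' @rdname positivityRule
#' @param object a PositivityRule.
#' @export
setMethod("show", "PositivityRule", function(object) {
  cat(sprintf("PositivityRule: positive when mean OD > %g (detection floor %g)\n",
              object@threshold, object@detectionFloor))
})

#' Classify nuclei as ER-positive or negative
#'
#' Sets \code{is_positive = mean_od > threshold}: strictly greater, so a
#' nucleus at exactly the cutoff is negative (OD values of 0.1 and less
#' belong to negative nuclei).
#'
#' @param measurements data.frame with a \code{mean_od} column (see
#'   [measureNucleus()]).
#' @param rule a [PositivityRule-class].
#' @return the measurements with \code{is_positive} filled in.
#' @export
classifyPositive <- function(measurements, rule = positivityRule()) {
  stopifnot(is(rule, "PositivityRule"))
  if (anyNA(measurements$mean_od))
    stop("scoring error: mean_od must be set on every measurement")
  measurements$is_positive <- measurements$mean_od > rule@threshold
  measurements
}

#' Percent of positive nuclei
#'
#' The total number of measured nuclei per case corresponds to 100\%.
#'
#' @param measurements classified measurement data.frame
#'   (\code{is_positive} set).
#' @return percent positive in \code{[0, 100]}.
#' @export
percentPositive <- function(measurements) {
  if (nrow(measurements) == 0L)
    stop("scoring error: no measured nuclei")
  if (anyNA(measurements$is_positive))
    stop("scoring error: measurements must be classified first")
  100 * sum(measurements$is_positive) / nrow(measurements)
}

#' Mean nuclear DAB intensity of a case
#'
#' Arithmetic mean of per-nucleus mean DAB OD over \emph{all} measured
#' nuclei, positive and negative alike. Averaging over all nuclei (not only
#' positives) is what makes the quantitative score's two addends commensurate
#' and is the reading consistent with published discordant-case tables, where
#' nearly fully positive cases carry mean ODs far below the 0.1 cutoff.
#'
#' @param measurements measurement data.frame with \code{mean_od} set.
#' @return mean DAB OD (dimensionless, typically in \code{[0, 1]}).
#' @export
meanIntensity <- function(measurements) {
  if (nrow(measurements) == 0L)
    stop("scoring error: no measured nuclei")
  mean(measurements$mean_od)
}

#' Quantitative ER score
#'
#' \deqn{score = (percent\ positive + 100 \times mean\ OD) / 20}
#'
#' Both addends live on a 0-100 scale (mean nuclear OD cannot exceed 1), so
#' the score spans \code{[0, 10]}, scaled for comparability with the 0-8
#' Allred total. Monotone nondecreasing in both arguments.
#'
#' @param percent percent of ER-positive nuclei, in \code{[0, 100]}.
#' @param meanOD mean nuclear DAB OD over all measured nuclei, >= 0.
#' @return the quantitative ER score.
#' @examples
#' quantitativeERScore(55, 0.00015836)  # 2.750792
#' @export
quantitativeERScore <- function(percent, meanOD) {
  if (any(percent < 0 | percent > 100))
    stop("input error: percent must lie in [0, 100]")
  if (any(meanOD < 0))
    stop("input error: meanOD must be non-negative")
  (percent + 100 * meanOD) / 20
}

#' Allred proportion score
#'
#' Maps percent-positive to the 0-5 Allred proportion scale: 0 for exactly
#' 0\%, 1 below 1\%, 2 for 1-10\%, 3 for (10, 33]\%, 4 for (33, 66]\%, and
#' 5 above 66\%. The published bin edges (1-10, 11-33, 34-66, >67) leave
#' integer gaps; each bin is extended down to the previous printed bound
#' (half-open intervals) so that every percentage maps to exactly one score.
#'
#' @param percent percent of positive nuclei, in \code{[0, 100]};
#'   vectorized.
#' @return integer score(s) 0-5.
#' @examples
#' allredProportionScore(c(0, 0.5, 5, 14, 55, 98))  # 0 1 2 3 4 5
#' @export
allredProportionScore <- function(percent) {
  if (any(is.na(percent)) || any(percent < 0 | percent > 100))
    stop("input error: percent must lie in [0, 100]")
  score <- integer(length(percent))
  score[percent > 0] <- 1L
  score[percent >= 1] <- 2L
  score[percent > 10] <- 3L
  score[percent > 33] <- 4L
  score[percent > 66] <- 5L
  score
}

#' Allred intensity score from mean nuclear OD
#'
#' Score 0 up to and including the 0.1-OD cutoff (the boundary below which
#' staining is not apparent to the eye); scores 1-3 partition the remaining
#' attainable range (OD <= 1) by the configurable \code{bins}: with the
#' defaults, (0.1, 0.4] -> 1 (weak), (0.4, 0.7] -> 2 (medium),
#' > 0.7 -> 3 (strong). Only the 0/1 boundary is anchored by the cutoff;
#' the 1/2 and 2/3 edges default to an even partition of the remaining
#' range.
#'
#' @param meanOD mean nuclear DAB OD, >= 0; vectorized.
#' @param bins numeric(3) increasing upper edges of scores 0, 1 and 2
#'   (default \code{c(0.1, 0.4, 0.7)}).
#' @return integer score(s) 0-3.
#' @export
allredIntensityScore <- function(meanOD, bins = c(0.1, 0.4, 0.7)) {
  if (any(is.na(meanOD)) || any(meanOD < 0))
    stop("input error: meanOD must be non-negative")
  if (length(bins) != 3L || is.unsorted(bins, strictly = TRUE))
    stop("input error: bins must be 3 strictly increasing OD edges")
  score <- integer(length(meanOD))
  score[meanOD > bins[1]] <- 1L
  score[meanOD > bins[2]] <- 2L
  score[meanOD > bins[3]] <- 3L
  score
}

#' Score a case from pooled nucleus measurements
#'
#' Composes classification, percent-positive, mean intensity, the
#' quantitative ER score and the Allred-compatible triple. A case is flagged
#' discordant when its proportion score is at least 3 while its intensity
#' score is 0 (totals 3+0, 4+0, 5+0): many positive nuclei whose faint DAB
#' is masked by the hematoxylin background and missed by eye.
#'
#' @param measurements measurement data.frame (classified or not; when
#'   \code{is_positive} is absent or NA, [classifyPositive()] is applied
#'   with \code{rule}).
#' @param rule a [PositivityRule-class].
#' @param caseId case label recorded in the result.
#' @param intensityBins passed to [allredIntensityScore()].
#' @return a [CaseScore-class].
#' @export
scoreCase <- function(measurements, rule = positivityRule(),
                      caseId = "case_1", intensityBins = c(0.1, 0.4, 0.7)) {
  if (nrow(measurements) == 0L)
    stop("scoring error: no measured nuclei")
  if (is.null(measurements$is_positive) || anyNA(measurements$is_positive))
    measurements <- classifyPositive(measurements, rule)
  pct <- percentPositive(measurements)
  mi <- meanIntensity(measurements)
  .caseScore(caseId, nrow(measurements), pct, mi, intensityBins)
}

#' Score a case from its summary values
#'
#' Builds a [CaseScore-class] directly from a case's percent-positive and
#' mean nuclear OD, e.g. when re-scoring published per-case tables where
#' the raw nucleus measurements are not available.
#'
#' @param percent percent of positive nuclei, \code{[0, 100]}.
#' @param meanOD mean nuclear DAB OD over all measured nuclei.
#' @param caseId case label.
#' @param intensityBins passed to [allredIntensityScore()].
#' @return a [CaseScore-class].
#' @examples
#' scoreFromSummary(14, 0.00002071)  # proportion 3, intensity 0: discordant
#' @export
scoreFromSummary <- function(percent, meanOD, caseId = "case_1",
                             intensityBins = c(0.1, 0.4, 0.7)) {
  .caseScore(caseId, NA_integer_, percent, meanOD, intensityBins)
}

.caseScore <- function(caseId, nNuclei, pct, mi, intensityBins) {
  qp <- allredProportionScore(pct)
  qi <- allredIntensityScore(mi, bins = intensityBins)
  new("CaseScore", caseId = as.character(caseId),
      nNuclei = as.integer(nNuclei),
      percentPositive = as.numeric(pct), meanIntensity = as.numeric(mi),
      quantitativeScore = quantitativeERScore(pct, mi),
      qProportion = qp, qIntensity = qi, qTotal = qp + qi,
      discordant = qp >= 3L && qi == 0L)
}

#' @rdname CaseScore-class
#' @param object a CaseScore.
#' @export
setMethod("show", "CaseScore", function(object) {
  cat(sprintf("CaseScore '%s': %s nuclei\n", object@caseId,
              ifelse(is.na(object@nNuclei), "summary-derived",
                     object@nNuclei)))
  cat(sprintf("  %% positive:        %.4f\n", object@percentPositive))
  cat(sprintf("  mean DAB OD:       %.5f\n", object@meanIntensity))
  cat(sprintf("  quantitative ER:   %.4f\n", object@quantitativeScore))
  cat(sprintf("  Allred-compatible: %d + %d = %d%s\n", object@qProportion,
              object@qIntensity, object@qTotal,
              if (object@discordant) "  [discordant]" else ""))
})

#' Convert a CaseScore to a one-row data.frame
#'
#' @param x a [CaseScore-class].
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return data.frame with columns case_id, n_nuclei, percent_positive,
#'   mean_intensity, quantitative_score, q_proportion_score,
#'   q_intensity_score, q_total, discordant.
#' @export
as.data.frame.CaseScore <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(case_id = x@caseId, n_nuclei = x@nNuclei,
             percent_positive = x@percentPositive,
             mean_intensity = x@meanIntensity,
             quantitative_score = x@quantitativeScore,
             q_proportion_score = x@qProportion,
             q_intensity_score = x@qIntensity,
             q_total = x@qTotal, discordant = x@discordant,
             stringsAsFactors = FALSE)
}

#' Accessors for CaseScore
#' @param x a [CaseScore-class].
#' @return the corresponding slot value.
#' @name caseScoreAccessors
NULL

#' @rdname caseScoreAccessors
#' @export
caseId <- function(x) x@caseId
#' @rdname caseScoreAccessors
#' @export
quantitativeScore <- function(x) x@quantitativeScore
#' @rdname caseScoreAccessors
#' @export
allredTriple <- function(x)
  c(proportion = x@qProportion, intensity = x@qIntensity, total = x@qTotal)
#' @rdname caseScoreAccessors
#' @export
isDiscordant <- function(x) x@discordant
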