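# Cohort-level statistics comparing semi-quantitative (pathologist) and
# quantitative scores: descriptives, Pearson correlation with significance,
# Cohen's d, histogram summaries and discordant-case listing.

#' Descriptive statistics of a numeric variable
#'
#' Mean, sample standard deviation (n - 1 denominator), median, minimum and
#' maximum.
#'
#' @param values numeric vector, at least 1 value (SD needs 2 and is NA for
#'   a single value).
#' @return named list with \code{mean}, \code{sd}, \code{median},
#'   \code{min}, \code{max}, \code{n}.
#' @export
cohortDescriptives <- function(values) {
  if (length(values) == 0L || anyNA(values))
    stop("stats error: need at least one non-missing value")
  list(mean = mean(values), sd = stats::sd(values),
       median = stats::median(values), min = min(values),
       max = max(values), n = length(values))
}

#' Pearson correlation with two-sided significance
#'
#' Product-moment correlation; the p-value comes from the two-sided t test
#' on \code{r * sqrt((n-2)/(1-r^2))} with n - 2 degrees of freedom. A p
#' value below 1e-15 (including exact collinearity, where the test
#' statistic is infinite) is reported as the machine floor 1e-15 together
#' with the rendering "< 0.001".
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with \code{r}, \code{p_value}, \code{n} and
#'   \code{p_label} (p rendered to 3 significant figures, or "< 0.001").
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y))
    stop("stats error: x and y must have equal length")
  if (length(x) < 3L)
    stop("stats error: need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("stats error: zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  p <- max(unname(ct$p.value), 1e-15)
  list(r = unname(ct$estimate), p_value = p, n = length(x),
       p_label = formatPValue(p))
}

#' Cohen's d with pooled sample SD
#'
#' \deqn{d = (\bar{x}_a - \bar{x}_b) / s_{pooled}, \quad
#'       s_{pooled} = \sqrt{((n_a-1)s_a^2 + (n_b-1)s_b^2) / (n_a+n_b-2)}}
#'
#' The sign follows \code{a - b}; |d| is invariant to rescaling both groups.
#'
#' @param a,b numeric vectors, each with at least 2 values.
#' @return Cohen's d.
#' @examples
#' cohensD(c(2, 4), c(1, 3))  # 0.7071068
#' @export
cohensD <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("stats error: each group needs at least 2 values")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0)
    stop("stats error: zero pooled standard deviation")
  (mean(a) - mean(b)) / sp
}

#' Render a p-value in reporting style
#'
#' Three significant figures, with values below 0.001 rendered as
#' \code{"< 0.001"}.
#'
#' @param p a p-value in (0, 1].
#' @return character label.
#' @export
formatPValue <- function(p) {
  if (p < 0.001) "< 0.001" else format(signif(p, 3), scientific = FALSE)
}

#' Compare semi-quantitative and quantitative scores across a cohort
#'
#' Takes a per-case cohort table pairing the pathologists' Allred scores
#' with the pipeline's quantitative results and computes: Pearson r/p and
#' Cohen's d between the semi-quantitative total and the quantitative ER
#' score; Pearson r/p between percent-positive and mean nuclear intensity;
#' histogram bin counts of both score distributions; and the list of
#' discordant cases (quantitative proportion score >= 3 with intensity
#' score 0).
#'
#' @param cohort data.frame with columns \code{case_id},
#'   \code{sq_proportion}, \code{sq_intensity}, \code{sq_total},
#'   \code{percent_positive}, \code{mean_intensity},
#'   \code{quantitative_score}.
#' @param intensityBins passed to [allredIntensityScore()] when flagging
#'   discordant cases.
#' @return list with components \code{score_correlation} (r, p, d between
#'   sq_total and quantitative_score), \code{intensity_vs_percent} (r, p),
#'   \code{histograms} (counts of sq_total over 0..8 and of the
#'   quantitative score over unit bins 0..10), \code{discordant_cases}
#'   (character vector of case ids) and \code{descriptives} (per-variable
#'   summaries).
#' @export
compareScores <- function(cohort, intensityBins = c(0.1, 0.4, 0.7)) {
  needed <- c("case_id", "sq_total", "percent_positive", "mean_intensity",
              "quantitative_score")
  missing <- setdiff(needed, names(cohort))
  if (length(missing))
    stop("stats error: cohort table lacks column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(cohort$case_id))
    stop("stats error: case ids must be unique")

  sc <- pearsonCorrelation(cohort$sq_total, cohort$quantitative_score)
  sc$d <- cohensD(cohort$sq_total, cohort$quantitative_score)
  ip <- pearsonCorrelation(cohort$percent_positive, cohort$mean_intensity)

  qp <- allredProportionScore(cohort$percent_positive)
  qi <- allredIntensityScore(cohort$mean_intensity, bins = intensityBins)
  discordant <- as.character(cohort$case_id[qp >= 3L & qi == 0L])

  sqCounts <- table(factor(cohort$sq_total, levels = 0:8))
  qBreaks <- 0:10
  qCounts <- table(cut(pmin(cohort$quantitative_score, 10), breaks = qBreaks,
                       include.lowest = TRUE, right = TRUE))

  list(
    score_correlation = sc,
    intensity_vs_percent = ip,
    histograms = list(
      sq_total = stats::setNames(as.integer(sqCounts), names(sqCounts)),
      quantitative_score = stats::setNames(as.integer(qCounts),
                                           names(qCounts))),
    discordant_cases = discordant,
    descriptives = list(
      sq_total = cohortDescriptives(cohort$sq_total),
      quantitative_score = cohortDescriptives(cohort$quantitative_score),
      percent_positive = cohortDescriptives(cohort$percent_positive),
      mean_intensity = cohortDescriptives(cohort$mean_intensity)))
}

#' Reference table of discordant ER cases
#'
#' A published set of 12 invasive lobular breast-carcinoma cases that were
#' allocated Allred score 0 by semi-quantitative reading, yet carried
#' measurable DAB after color deconvolution: per case, the mean nuclear
#' stain intensity (OD) and the percent of ER-positive nuclei under a
#' detection-floor positivity reading. Re-scoring these rows with
#' [scoreFromSummary()] surfaces the discordant 3+0, 4+0 and 5+0 totals.
#'
#' @return data.frame with columns \code{case_id}, \code{mean_intensity},
#'   \code{percent_positive}.
#' @examples
#' ref <- discordantReferenceCases()
#' scoreFromSummary(ref$percent_positive[3], ref$mean_intensity[3],
#'                  caseId = ref$case_id[3])
#' @export
discordantReferenceCases <- function() {
  path <- system.file("extdata", "discordant_reference_cases.csv",
                      package = "erquant", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
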