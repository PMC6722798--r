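# Positivity classification, the quantitative ER score and the
# Allred-compatible mapping with discordance detection.

test_that("positivity is strict: OD at the cutoff is negative", {
  m <- fakeMeasurements(c(0, 0.10, 0.11))
  cls <- classifyPositive(m, positivityRule(0.1))
  expect_equal(cls$is_positive, c(FALSE, FALSE, TRUE))
})

test_that("percent positive counts all measured nuclei as 100%", {
  m <- classifyPositive(fakeMeasurements(rep(0.05, 50)))
  expect_equal(percentPositive(m), 0)
  m2 <- classifyPositive(fakeMeasurements(c(rep(0.5, 25), rep(0, 25))))
  expect_equal(percentPositive(m2), 50)
  m3 <- classifyPositive(fakeMeasurements(c(rep(0.5, 7), rep(0, 5))))
  expect_equal(percentPositive(m3), 100 * 7 / 12)
  expect_error(percentPositive(fakeMeasurements(numeric(0))),
               "scoring error")
})

test_that("mean intensity averages all nuclei and reproduces the reference-table summary", {
  expect_equal(meanIntensity(fakeMeasurements(c(0, 0, 0))), 0)
  expect_equal(meanIntensity(fakeMeasurements(c(0.2, 0.4))), 0.3)
  ref <- discordantReferenceCases()
  expect_equal(signif(meanIntensity(fakeMeasurements(ref$mean_intensity)), 2),
               0.0024)
})

test_that("the quantitative ER score follows (percent + 100*meanOD)/20 and is monotone", {
  expect_equal(quantitativeERScore(0, 0), 0)
  expect_equal(quantitativeERScore(100, 1), 10)
  expect_equal(quantitativeERScore(55, 0.00015836), 2.7507918)
  expect_error(quantitativeERScore(101, 0), "input error")
  pcts <- seq(0, 100, by = 5)
  expect_true(all(diff(quantitativeERScore(pcts, 0.3)) >= 0))
  ods <- seq(0, 1, by = 0.05)
  expect_true(all(diff(quantitativeERScore(40, ods)) >= 0))
})

test_that("the proportion score is a total, nondecreasing step map of percent", {
  expect_equal(allredProportionScore(c(0, 0.5, 1, 5, 10, 14, 33, 34, 55,
                                       66, 67, 98, 100)),
               c(0L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 5L, 5L, 5L))
  pcts <- sort(c(seq(0, 100, length.out = 401),
                 10 + 1e-9, 33 + 1e-9, 66 + 1e-9))
  scores <- allredProportionScore(pcts)
  expect_true(all(diff(scores) >= 0))          # nondecreasing
  expect_true(all(scores %in% 0:5))            # total, no gaps
  expect_error(allredProportionScore(-1), "input error")
})

test_that("the intensity score is 0 at and below the 0.1-OD cutoff and binned above it", {
  expect_equal(allredIntensityScore(c(0, 0.05, 0.1, 0.25, 0.4, 0.55, 0.7,
                                      0.75, 1)),
               c(0L, 0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(allredIntensityScore(0.35, bins = c(0.1, 0.2, 0.3)), 3L)
  expect_error(allredIntensityScore(-0.1), "input error")
})

test_that("scoring the reference discordant cases yields the 3+0, 4+0 and 5+0 totals", {
  ref <- discordantReferenceCases()
  sc3 <- scoreFromSummary(ref$percent_positive[3], ref$mean_intensity[3],
                          caseId = ref$case_id[3])
  expect_equal(unname(allredTriple(sc3)), c(3L, 0L, 3L))
  expect_true(isDiscordant(sc3))

  sc1 <- scoreFromSummary(ref$percent_positive[1], ref$mean_intensity[1])
  expect_equal(unname(allredTriple(sc1)), c(4L, 0L, 4L))
  expect_true(isDiscordant(sc1))

  sc10 <- scoreFromSummary(ref$percent_positive[10], ref$mean_intensity[10])
  expect_equal(unname(allredTriple(sc10)), c(5L, 0L, 5L))
  expect_true(isDiscordant(sc10))

  sc8 <- scoreFromSummary(ref$percent_positive[8], ref$mean_intensity[8])
  expect_equal(unname(allredTriple(sc8)), c(0L, 0L, 0L))
  expect_false(isDiscordant(sc8))
})

test_that("scoreCase composes the pieces and flags discordance from measurements", {
  # 40% of nuclei carry faint but detectable DAB (< 0.1 OD): under the
  # detection-floor reading these count as positive yet intensity stays 0
  ods <- c(rep(0.04, 40), rep(0, 60))
  m <- fakeMeasurements(ods)
  floorRule <- positivityRule(threshold = 0, detectionFloor = 0)
  sc <- scoreCase(m, floorRule, caseId = "faint")
  expect_equal(sc@percentPositive, 40)
  expect_equal(unname(allredTriple(sc)), c(4L, 0L, 4L))
  expect_true(isDiscordant(sc))
  expect_equal(quantitativeScore(sc),
               (40 + 100 * mean(ods)) / 20)

  # with the standard 0.1 threshold the same case is 0 + 0
  sc0 <- scoreCase(m, positivityRule(0.1), caseId = "faint")
  expect_equal(sc0@percentPositive, 0)
  expect_false(isDiscordant(sc0))
})

test_that("raising the positivity threshold never increases percent positive", {
  set.seed(21)
  m <- fakeMeasurements(runif(200, 0, 0.6))
  pcts <- vapply(seq(0, 0.6, by = 0.05), function(thr)
    percentPositive(classifyPositive(m, positivityRule(thr))), numeric(1))
  expect_true(all(diff(pcts) <= 0))
})

test_that("CaseScore validity enforces the score identities", {
  expect_error(new("CaseScore", caseId = "x", nNuclei = 1L,
                   percentPositive = 50, meanIntensity = 0.2,
                   quantitativeScore = 9, qProportion = 4L,
                   qIntensity = 1L, qTotal = 5L, discordant = FALSE),
               "quantitativeScore")
  df <- as.data.frame(scoreFromSummary(50, 0.2, caseId = "x"))
  expect_equal(df$quantitative_score, 3.5)
  expect_equal(df$q_total, df$q_proportion_score + df$q_intensity_score)
})
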