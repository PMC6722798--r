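# Forward-model generator: determinism, ground-truth recovery through the
# full pipeline, and cohort-level structure.

test_that("rendering is bit-identical for a fixed seed and differs across fields", {
  spec <- syntheticCaseSpec(nNuclei = 20, seed = 99L)
  f1 <- renderField(spec, 1)
  f2 <- renderField(spec, 1)
  expect_identical(imagePixels(f1$image), imagePixels(f2$image))
  expect_identical(f1$truth, f2$truth)
  f3 <- renderField(spec, 2)
  expect_false(identical(imagePixels(f1$image), imagePixels(f3$image)))
})

test_that("with all DAB at zero the deconvolved DAB map is zero up to quantization", {
  spec <- syntheticCaseSpec(nNuclei = 20, truePositiveFraction = 0,
                            seed = 3L)
  fld <- renderField(spec, 1)
  dab <- dabMap(deconvolveStains(rgbToOD(fld$image)))
  expect_lt(max(dab), 0.02)
})

test_that("a single nucleus with DAB OD 0.5 measures within 2% after the full pipeline", {
  spec <- syntheticCaseSpec(nNuclei = 1, truePositiveFraction = 1,
                            dabOdPositive = c(0.5, 0), seed = 8L)
  fld <- renderField(spec, 1)
  dab <- dabMap(deconvolveStains(rgbToOD(fld$image)))
  m <- measureNucleus(dab, fld$rois)
  expect_lt(abs(m$mean_od - 0.5) / 0.5, 0.02)
})

test_that("generated nuclei respect the configured axis range and do not overlap", {
  spec <- syntheticCaseSpec(nNuclei = 40, axisRange = c(8, 20), seed = 17L)
  t <- renderField(spec, 1)$truth
  expect_true(all(t$a >= 4 & t$a <= 10))
  expect_true(all(t$b >= 4 & t$b <= 10))
  d <- as.matrix(dist(cbind(t$cx, t$cy)))
  rmax <- pmax(t$a, t$b)
  sep <- outer(rmax, rmax, `+`)
  diag(d) <- Inf
  expect_true(all(d > sep))
  cramped <- syntheticCaseSpec(nNuclei = 60, width = 50, height = 50,
                               seed = 1L)
  expect_error(renderField(cramped), "infeasible packing")
})

test_that("ground-truth labels are consistent with the positivity threshold", {
  spec <- syntheticCaseSpec(nNuclei = 60, truePositiveFraction = 0.35,
                            dabOdNegative = c(0.05, 0.03), seed = 23L)
  t <- renderField(spec, 1)$truth
  expect_equal(sum(t$is_positive), round(0.35 * 60))
  expect_true(all(t$dab_od[t$is_positive] > 0.1))
  expect_true(all(t$dab_od[!t$is_positive] <= 0.1))
})

test_that("clean well-separated cases recover percent positive exactly among sampled nuclei", {
  spec <- syntheticCaseSpec(nNuclei = 40, nFields = 3,
                            truePositiveFraction = 0.4,
                            dabOdPositive = c(0.5, 0), seed = 29L)
  res <- scoreSyntheticCase(spec)
  expect_equal(res$score@percentPositive,
               res$truthSelected$percent_positive)
  expect_equal(res$score@nNuclei, res$truthSelected$n)
})

test_that("percent positive recovers the generator parameter within the binomial bound at ~500 nuclei", {
  spec <- syntheticCaseSpec(nNuclei = 50, nFields = 10,
                            truePositiveFraction = 0.4, seed = 37L)
  res <- scoreSyntheticCase(spec)
  expect_gt(res$score@nNuclei, 200)
  expect_lt(abs(res$score@percentPositive - 40), 4)
})

test_that("a faint-DAB case surfaces as 3+0 discordant under detection-floor positivity", {
  # ~14% of nuclei carry detectable DAB far below the 0.1 cutoff
  spec <- syntheticCaseSpec(nNuclei = 50, nFields = 10,
                            truePositiveFraction = 0.14,
                            dabOdPositive = c(0.05, 0.01),
                            positivityThreshold = 0.02, seed = 43L)
  res <- scoreSyntheticCase(spec, rule = positivityRule(0.02, 0.02))
  expect_equal(res$score@qProportion, 3L)
  expect_equal(res$score@qIntensity, 0L)
  expect_true(isDiscordant(res$score))
})

test_that("synthetic cohorts are reproducible and strongly linked across score systems", {
  cohort <- generateCohort(12, seed = 61L, nNuclei = 30, nFields = 3)
  cohort2 <- generateCohort(12, seed = 61L, nNuclei = 30, nFields = 3)
  expect_identical(cohort, cohort2)
  expect_equal(nrow(cohort), 12L)
  # quantitative score column equals the formula recomputed from its parts
  expect_equal(cohort$quantitative_score,
               (cohort$percent_positive + 100 * cohort$mean_intensity) / 20)
  res <- compareScores(cohort)
  expect_gt(res$score_correlation$r, 0.8)
})
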