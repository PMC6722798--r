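# Beer-Lambert OD transform and H-DAB deconvolution.

odOf <- function(intensity, whiteRef = 255) {
  img <- RGBImage(array(intensity, dim = c(1, 1, 3)), whiteRef = whiteRef)
  odValues(rgbToOD(img))[1, 1, 1]
}

test_that("OD calibration: blank pixel is 0, 90% absorption is OD 1, 99% is OD 2", {
  expect_equal(odOf(255), 0)
  expect_equal(odOf(25.5), 1)   # 10% transmitted = 90% absorbed
  expect_equal(odOf(2.55), 2)   # 1% transmitted = 99% absorbed
})

test_that("OD is non-negative, finite at zero intensity, strictly decreasing in intensity", {
  ints <- seq(0, 255, by = 5)
  ods <- vapply(ints, odOf, numeric(1))
  expect_true(all(ods >= 0))
  expect_true(all(is.finite(ods)))
  expect_true(all(diff(ods) < 0 | (ints[-1] <= 1)))  # flat only under the floor
  expect_lt(odOf(0), 2.5)  # epsilon floor caps black pixels near OD 2.4
})

test_that("non-positive white reference is a calibration error", {
  expect_error(RGBImage(array(1, dim = c(1, 1, 3)), whiteRef = 0),
               "calibration")
})

test_that("stain matrix construction normalizes, is scale invariant, and completes the residual", {
  m <- stainMatrix(c(1, 0, 0), c(0, 1, 0))
  expect_equal(unname(stainVectors(m)), diag(3))
  m2 <- stainMatrix(c(2, 0, 0), c(0, 3, 0))
  expect_equal(stainVectors(m2), stainVectors(m))
  expect_error(stainMatrix(c(1, 1, 0), c(2, 2, 0)), "collinear")
})

test_that("default H-DAB preset has unit rows and a well-conditioned matrix", {
  M <- stainVectors(hdabStainMatrix())
  expect_equal(unname(sqrt(rowSums(M^2))), rep(1, 3), tolerance = 1e-12)
  expect_lt(kappa(M, exact = TRUE), 10)
})

test_that("deconvolution recovers pure-stain pixels and maps zero OD to zero", {
  m <- hdabStainMatrix()
  dabRow <- stainVectors(m)["dab", ]
  c0 <- 0.7
  od <- new("ODImage", od = array(rep(c0 * dabRow, each = 6),
                                  dim = c(2, 3, 3)))
  maps <- deconvolveStains(od, m)
  expect_equal(dabMap(maps), matrix(c0, 2, 3), tolerance = 1e-12)
  expect_equal(hematoxylinMap(maps), matrix(0, 2, 3), tolerance = 1e-12)

  zero <- new("ODImage", od = array(0, dim = c(2, 3, 3)))
  mz <- deconvolveStains(zero, m)
  expect_equal(dabMap(mz), matrix(0, 2, 3))
  expect_equal(hematoxylinMap(mz), matrix(0, 2, 3))
})

test_that("deconvolution is linear before clamping: doubling OD doubles concentrations", {
  m <- hdabStainMatrix()
  set.seed(11)
  conc <- cbind(runif(24, 0, 1), runif(24, 0, 1), 0)
  od1 <- array(conc %*% stainVectors(m), dim = c(4, 6, 3))
  maps1 <- deconvolveStains(new("ODImage", od = od1), m)
  maps2 <- deconvolveStains(new("ODImage", od = 2 * od1), m)
  expect_equal(dabMap(maps2), 2 * dabMap(maps1), tolerance = 1e-9)
  expect_equal(hematoxylinMap(maps2), 2 * hematoxylinMap(maps1),
               tolerance = 1e-9)
})

test_that("forward model: zero maps give the white reference; a pure unit-OD stain scales one channel", {
  blank <- stainMaps(matrix(0, 2, 2), matrix(0, 2, 2))
  img <- reconstructRGB(blank, hdabStainMatrix(), whiteRef = 255)
  expect_true(all(imagePixels(img) == 255))

  mAxes <- stainMatrix(c(1, 0, 0), c(0, 1, 0))
  one <- stainMaps(matrix(0, 1, 1), matrix(1, 1, 1))
  px <- imagePixels(reconstructRGB(one, mAxes, whiteRef = 255))
  expect_equal(as.numeric(px), c(255, 26, 255))  # 25.5 rounds to 26
})

test_that("round trip reconstruct -> od -> deconvolve recovers concentrations within 8-bit tolerance", {
  m <- hdabStainMatrix()
  set.seed(7)
  n <- 40 * 40
  ch <- runif(n, 0, 2); cd <- runif(n, 0, 2)
  maps <- stainMaps(matrix(ch, 40, 40), matrix(cd, 40, 40))
  rec <- deconvolveStains(rgbToOD(reconstructRGB(maps, m)), m)
  keep <- ch >= 0.05
  relH <- abs(as.vector(hematoxylinMap(rec)) - ch)[keep] / ch[keep]
  keep2 <- cd >= 0.05
  relD <- abs(as.vector(dabMap(rec)) - cd)[keep2] / cd[keep2]
  expect_lt(mean(relH), 0.02)
  expect_lt(mean(relD), 0.02)
})
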