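# Grid construction, stereological nucleus selection and ROI measurement.

test_that("grid crosses sit at cell centers with the exact count", {
  g <- makeGrid(240, 180, 24, 18)
  pts <- gridPoints(g)
  expect_equal(nrow(pts), 432L)
  expect_equal(unname(pts[1, ]), c(5, 5))
  xs <- sort(unique(pts[, 1]))
  expect_equal(min(diff(xs)), 240 / 24)
  expect_true(all(pts[, 1] > 0 & pts[, 1] < 240))
  expect_true(all(pts[, 2] > 0 & pts[, 2] < 180))

  g1 <- makeGrid(100, 60, 1, 1)
  expect_equal(unname(gridPoints(g1)[1, ]), c(50, 30))
  expect_error(makeGrid(-10, 50), "input error")
  expect_error(makeGrid(10, 50, nx = 24, ny = 18), "input error")
})

test_that("a nucleus hit by many crosses is selected once; a missed one not at all", {
  g <- makeGrid(240, 180, 24, 18)
  whole <- cbind(x = c(0, 240, 240, 0), y = c(0, 0, 180, 180))
  # strictly between crosses: the first cell's crosses are at x,y = 5
  tiny <- cbind(x = c(6, 8, 8, 6), y = c(6, 6, 8, 8))
  rois <- roiSet(list(whole, tiny), ids = c("all", "tiny"))
  sel <- selectNuclei(g, rois)
  expect_equal(roiIds(sel), "all")
  expect_equal(length(sel), 1L)
})

test_that("selection preserves input order and agrees with the winding-number brute-force oracle", {
  g <- makeGrid(240, 180, 24, 18)
  set.seed(13)
  polys <- lapply(seq_len(100), function(i)
    discPolygon(runif(1, 5, 235), runif(1, 5, 175), runif(1, 1.5, 6),
                nVertices = sample(8:24, 1)))
  rois <- roiSet(polys, ids = sprintf("d%03d", 1:100))
  sel <- roiIds(selectNuclei(g, rois))
  expect_equal(sel, bruteForceSelect(g, rois))
  expect_equal(sel, sort(sel))  # ids were assigned in order
})

test_that("mean OD over a polygon matches direct pixel counting", {
  dab <- matrix(0.5, nrow = 20, ncol = 30)
  anyRoi <- discPolygon(15, 10, 5)
  m <- measureNucleus(dab, anyRoi)
  expect_equal(m$mean_od, 0.5)
  expect_true(is.na(m$is_positive))

  zeros <- matrix(0, 20, 30)
  expect_equal(measureNucleus(zeros, anyRoi)$mean_od, 0)

  # half 0, half 0.4: rectangle covering columns 0..19 (10 of each half)
  half <- cbind(matrix(0, 20, 10), matrix(0.4, 20, 20))
  rect <- cbind(x = c(0, 20, 20, 0), y = c(0, 0, 20, 20))
  mh <- measureNucleus(half, rect)
  expect_equal(mh$pixel_count, 400L)
  expect_equal(mh$mean_od, 0.2)
})

test_that("measurement is invariant under polygon vertex rotation", {
  set.seed(5)
  dab <- matrix(runif(600), nrow = 20, ncol = 30)
  poly <- discPolygon(14, 9, 6, nVertices = 15L)
  base <- measureNucleus(dab, poly)
  for (shift in c(3, 7, 11)) {
    rotated <- poly[c((shift + 1):nrow(poly), 1:shift), ]
    m <- measureNucleus(dab, rotated)
    expect_equal(m$mean_od, base$mean_od)
    expect_equal(m$pixel_count, base$pixel_count)
  }
})

test_that("ROIs outside the image or without pixel centers are measurement errors", {
  dab <- matrix(0, 10, 10)
  outside <- cbind(x = c(20, 25, 25, 20), y = c(20, 20, 25, 25))
  expect_error(measureNucleus(dab, outside), "outside")
  sliver <- cbind(x = c(1.1, 1.4, 1.4, 1.1), y = c(1.1, 1.1, 1.4, 1.4))
  expect_error(measureNucleus(dab, sliver), "no pixel centers")
})

test_that("pooling concatenates fields unchanged and warns below the field minimum", {
  fields <- lapply(1:10, function(f) fakeMeasurements(rep(0.2, 5)))
  pooled <- expect_silent(poolFields(fields))
  expect_equal(nrow(pooled), 50L)

  expect_warning(p3 <- poolFields(fields[1:3]), "3 field")
  expect_equal(nrow(p3), 15L)
  expect_equal(sort(p3$mean_od), sort(unlist(lapply(fields[1:3],
                                                    `[[`, "mean_od"))))
  expect_warning(p0 <- poolFields(list()), "0 field")
  expect_equal(nrow(p0), 0L)
})

test_that("ROISet validity rejects degenerate and duplicate outlines", {
  sq <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  expect_error(roiSet(list(sq, sq), ids = c("a", "a")), "duplicate")
  expect_error(roiSet(list(sq[1:2, ])), "3 vertices")
  bowtie <- cbind(x = c(0, 10, 0, 10), y = c(0, 10, 10, 0))
  expect_error(roiSet(list(bowtie)), "self-intersecting")
})
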