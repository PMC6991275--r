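test_that("window grid offsets follow (extent - window)/step + 1", {
  g <- buildWindowGrid(c(12, 12), c(500L, 500L), 3, 1.5)
  expect_equal(nrow(g@windows), 49L)              # 7 offsets per axis
  g6 <- buildWindowGrid(c(6, 6), c(200L, 200L), 3, 1.5)
  expect_equal(nrow(g6@windows), 9L)
  g1 <- buildWindowGrid(c(3, 3), c(100L, 100L), 3, 1.5)
  expect_equal(nrow(g1@windows), 1L)
  expect_error(buildWindowGrid(c(2, 2), c(64L, 64L), 3, 1.5), "larger")
})

test_that("every pixel is covered; interior pixels see exactly 4 windows", {
  g <- buildWindowGrid(c(12, 12), c(500L, 500L))
  cover <- matrix(0L, 500, 500)
  for (i in seq_len(nrow(g@windows))) {
    w <- g@windows[i, ]
    cover[w[1]:w[2], w[3]:w[4]] <- cover[w[1]:w[2], w[3]:w[4]] + 1L
  }
  expect_true(all(cover >= 1L))
  interior <- cover[150:350, 150:350]             # away from the border band
  expect_true(all(interior == 4L))
})

test_that("border-flush window fires when the step does not divide the field", {
  g <- buildWindowGrid(c(10, 10), c(100L, 100L), 3, 1.5)
  # offsets 0..6 by 1.5 reach 6, last window must end flush at 10 mm
  cover <- matrix(0L, 100, 100)
  for (i in seq_len(nrow(g@windows))) {
    w <- g@windows[i, ]
    cover[w[1]:w[2], w[3]:w[4]] <- cover[w[1]:w[2], w[3]:w[4]] + 1L
  }
  expect_true(all(cover >= 1L))
})

test_that("the window threshold is 0.35 of the large-vessel mean intensity", {
  n <- 100L
  px <- matrix(0.1, n, n)
  lv <- matrix(FALSE, n, n); lv[40:60, 40:60] <- TRUE
  px[lv] <- 0.8
  img <- new("Angiogram", pixels = px, extentMM = c(3, 3))
  grid <- buildWindowGrid(c(3, 3), c(n, n), 3, 1.5)  # single window
  tw <- windowThresholds(img, binaryMask(lv, c(3, 3)), grid)
  expect_equal(nrow(tw), 1L)
  expect_equal(tw$threshold, 0.35 * 0.8, tolerance = 1e-12)
})

test_that("an image bright only inside vessels yields an empty capillary mask", {
  n <- 100L
  lv <- matrix(FALSE, n, n); lv[30:70, 30:70] <- TRUE
  px <- ifelse(lv, 1, 0)
  img <- new("Angiogram", pixels = px, extentMM = c(6, 6))
  cap <- segmentCapillaries(img, binaryMask(lv, c(6, 6)))
  expect_false(any(pixels(cap)))
})

test_that("an empty large-vessel mask is a hard error, not a silent fallback", {
  img <- tubeImage()
  lv <- binaryMask(matrix(FALSE, 96, 96), c(12, 12))
  expect_error(segmentCapillaries(img, lv), "empty")
})

test_that("capillary and vessel masks are disjoint and votes are deterministic", {
  ph <- generatePhantom(phantomConfig(gridPx = c(250L, 250L), seed = 9))
  lv <- binaryMask(pixels(ph$truth@lvTruth), c(12, 12))
  c1 <- segmentCapillaries(ph$angiogram, lv)
  c2 <- segmentCapillaries(ph$angiogram, lv)
  expect_identical(pixels(c1), pixels(c2))
  expect_false(any(pixels(c1) & pixels(lv)))
})

test_that("segmented capillary fraction tracks the phantom fill fraction", {
  ph <- generatePhantom(phantomConfig(seed = 13, capillaryFillFraction = 0.55,
                                      speckleSigma = 0))
  lv <- ph$truth@lvTruth
  cap <- segmentCapillaries(ph$angiogram, lv)
  nonVessel <- !pixels(lv)
  frac <- sum(pixels(cap)[nonVessel]) / sum(nonVessel)
  expect_lt(abs(frac - 0.55), 0.10)
})

test_that("raising intensities inside one window only changes covered pixels", {
  ph <- generatePhantom(phantomConfig(gridPx = c(250L, 250L), seed = 10,
                                      speckleSigma = 0))
  lv <- ph$truth@lvTruth
  grid <- buildWindowGrid(c(12, 12), c(250L, 250L))
  base <- pixels(segmentCapillaries(ph$angiogram, lv, grid))
  px <- pixels(ph$angiogram)
  w <- grid@windows[25, ]                          # a central window
  px[w[1]:w[2], w[3]:w[4]] <- pmin(1, px[w[1]:w[2], w[3]:w[4]] + 0.2)
  bumped <- new("Angiogram", pixels = px, extentMM = c(12, 12))
  after <- pixels(segmentCapillaries(bumped, lv, grid))
  cover <- matrix(FALSE, 250, 250)
  for (i in seq_len(nrow(grid@windows))) {
    v <- grid@windows[i, ]
    # windows intersecting the modified one cover the pixels allowed to change
    if (v[1] <= w[2] && v[2] >= w[1] && v[3] <= w[4] && v[4] >= w[3])
      cover[v[1]:v[2], v[3]:v[4]] <- TRUE
  }
  expect_true(all(base[!cover] == after[!cover]))
})

test_that("low-signal masking flags a dark quadrant and spares uniform images", {
  u <- new("StructuralImage", pixels = matrix(0.8, 200, 200),
           extentMM = c(12, 12))
  expect_false(any(pixels(lowSignalMask(u))))

  px <- matrix(0.8, 200, 200); px[1:100, 1:100] <- 0.05
  s <- new("StructuralImage", pixels = px, extentMM = c(12, 12))
  flag <- pixels(lowSignalMask(s, capillaryParams(lowSignalQuantile = 0.25)))
  truth <- matrix(FALSE, 200, 200); truth[1:100, 1:100] <- TRUE
  expect_gte(diceCoef(flag, truth), 0.9)
})
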