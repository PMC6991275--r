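mkSeg <- function(lv, cap, extent = c(12, 12), lowSig = NULL) {
  segmentationResult(binaryMask(lv, extent), binaryMask(cap, extent),
                     lowSignal = if (is.null(lowSig)) NULL
                                 else binaryMask(lowSig, extent))
}

test_that("nonperfusion is the exact complement of perfusion in the valid area", {
  n <- 64L
  lv <- matrix(FALSE, n, n); lv[1:10, ] <- TRUE
  cap <- matrix(FALSE, n, n); cap[11:40, ] <- TRUE
  np <- pixels(nonperfusionMap(mkSeg(lv, cap)))
  expect_identical(np, !(lv | cap))

  full <- pixels(nonperfusionMap(mkSeg(matrix(TRUE, n, n), matrix(FALSE, n, n))))
  expect_false(any(full))
  none <- pixels(nonperfusionMap(mkSeg(matrix(FALSE, n, n), matrix(FALSE, n, n))))
  expect_true(all(none))

  chk <- outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2 == 0)
  np2 <- pixels(nonperfusionMap(mkSeg(matrix(FALSE, n, n), chk)))
  expect_identical(np2, !chk)

  ls <- matrix(FALSE, n, n); ls[50:64, 50:64] <- TRUE
  np3 <- pixels(nonperfusionMap(mkSeg(lv, cap, lowSig = ls)))
  expect_false(any(np3 & ls))
})

test_that("the 0.36 mm2 rule is strict at 24 um pixels", {
  # 500 px over 12 mm -> 0.024 mm pixels; 0.36 mm2 is exactly 625 px
  mk <- function(npx) {
    # 25x25 block minus/plus pixels so the component has exactly npx pixels
    m <- matrix(FALSE, 500, 500)
    m[101:125, 101:125] <- TRUE
    if (npx < 625L) m[101:(101 + 624L - npx), 101] <- FALSE
    if (npx > 625L) m[101:(101 + npx - 626L), 126] <- TRUE
    stopifnot(sum(m) == npx)
    binaryMask(m, c(12, 12))
  }
  expect_equal(nrow(detectDropout(mk(624))), 0L)   # 0.3594 mm2 rejected
  expect_equal(nrow(detectDropout(mk(625))), 0L)   # exactly 0.36 rejected
  r <- detectDropout(mk(626))                      # 0.3606 mm2 kept
  expect_equal(nrow(r), 1L)
  expect_equal(r$area_mm2, 626 * 0.024^2, tolerance = 1e-12)
  expect_equal(r$pixel_count, 626L)
})

test_that("components touching the FAZ mask are removed whole", {
  m <- matrix(FALSE, 200, 200)
  m[50:120, 50:120] <- TRUE                        # big central component
  m[150:190, 150:190] <- TRUE                      # separate peripheral one
  np <- binaryMask(m, c(12, 12))
  faz <- matrix(FALSE, 200, 200); faz[120, 120] <- TRUE   # 1 px overlap
  r <- detectDropout(np, faz = binaryMask(faz, c(12, 12)))
  expect_equal(nrow(r), 1L)
  expect_equal(r$pixel_count, 41L * 41L)
  # pixel mode keeps the rest of the touching component
  r2 <- detectDropout(np, faz = binaryMask(faz, c(12, 12)),
                      mode = "remove_pixels")
  expect_equal(nrow(r2), 2L)
})

test_that("dropout regions rasterise and re-detect to the same set", {
  set.seed(99)
  m <- matrix(runif(200 * 200) < 0.45, 200, 200)
  np <- binaryMask(m, c(12, 12))
  r <- detectDropout(np)
  expect_true(all(r$area_mm2 > 0.36))
  dm <- dropoutMask(r)
  expect_equal(sum(pixels(dm)), sum(r$pixel_count))
  r2 <- detectDropout(dm)
  expect_equal(nrow(r2), nrow(r))
  expect_equal(sort(r2$pixel_count), sort(r$pixel_count))
  expect_equal(sort(r2$centroid_x_mm), sort(r$centroid_x_mm), tolerance = 1e-9)
})

test_that("centroids and border flags are in field coordinates", {
  m <- matrix(FALSE, 100, 100)
  m[1:30, 41:60] <- TRUE                           # touches the top border
  np <- binaryMask(m, c(10, 10))                   # 0.1 mm pixels
  r <- detectDropout(np)
  expect_true(r$touches_border)
  expect_equal(r$centroid_x_mm, mean((41:60 - 0.5) * 0.1), tolerance = 1e-9)
  expect_equal(r$centroid_y_mm, mean((1:30 - 0.5) * 0.1), tolerance = 1e-9)
  r2 <- detectDropout(np, keepBorder = FALSE)
  expect_equal(nrow(r2), 0L)
})
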