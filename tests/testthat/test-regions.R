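test_that("region registry has the canonical geometry and nominal areas", {
  regs <- buildRegions(c(12, 12), c(500L, 500L))
  expect_equal(length(regs), 28L)
  expect_equal(regs$wide$nominalAreaMM2, 144)
  expect_equal(regs$central6$nominalAreaMM2, 36)
  expect_equal(regs$annulus$nominalAreaMM2, 108)         # 144 - 36
  expect_equal(regs$block_0_0$nominalAreaMM2, 5.76)      # 2.4 mm blocks
  # realized pixel areas match nominal (pixel centres partition exactly)
  expect_equal(regs$central6$areaMM2, 36, tolerance = 1e-9)
  expect_equal(regs$annulus$areaMM2, 108, tolerance = 1e-9)
  # central + annulus = wide, disjoint
  expect_identical(regs$central6$mask | regs$annulus$mask, regs$wide$mask)
  expect_false(any(regs$central6$mask & regs$annulus$mask))
  # the 25 blocks partition the wide field exactly
  bsum <- Reduce(`+`, lapply(grep("^block_", names(regs), value = TRUE),
                             function(n) regs[[n]]$mask * 1L))
  expect_true(all(bsum == 1L))
  expect_error(buildRegions(c(12, 12), c(100L, 100L), centralMM = 13),
               "smaller")
})

test_that("metrics follow hand counts on a toy segmentation", {
  n <- 10L
  lv <- matrix(FALSE, n, n); lv[1:2, ] <- TRUE           # 20 px
  cap <- matrix(FALSE, n, n); cap[3:5, ] <- TRUE         # 30 px
  seg <- segmentationResult(binaryMask(lv, c(1, 1)), binaryMask(cap, c(1, 1)))
  reg <- list(name = "wide", mask = matrix(TRUE, n, n),
              validMask = matrix(TRUE, n, n), areaMM2 = 1)
  rec <- computeMetrics(seg, NULL, reg)
  expect_equal(rec$LVD_pct, 20)
  expect_equal(rec$CPD_pct, 30)
  expect_equal(rec$TPD_pct, 50)
  expect_equal(rec$CDD_pct, 0)

  segFull <- segmentationResult(binaryMask(lv, c(1, 1)),
                                binaryMask(!lv, c(1, 1)))
  recF <- computeMetrics(segFull, NULL, reg)
  expect_equal(recF$TPD_pct, 100)
})

test_that("excluded pixels leave numerator and denominator together", {
  n <- 100L
  lv <- matrix(FALSE, n, n); lv[, 1:10] <- TRUE
  cap <- matrix(FALSE, n, n); cap[, 11:60] <- TRUE
  ls <- matrix(FALSE, n, n); ls[1:50, ] <- TRUE          # top half low signal
  seg <- segmentationResult(binaryMask(lv, c(12, 12)),
                            binaryMask(cap, c(12, 12)),
                            lowSignal = binaryMask(ls, c(12, 12)))
  regs <- buildRegions(c(12, 12), c(n, n),
                       lowSignal = binaryMask(ls, c(12, 12)))
  rec <- computeMetrics(seg, NULL, regs$wide)
  # bottom half only: 10% vessels, 50% capillaries of the valid area
  expect_equal(rec$LVD_pct, 10)
  expect_equal(rec$CPD_pct, 50)
  expect_equal(rec$valid_area_mm2, 72, tolerance = 1e-9)
})

test_that("area-weighted block metrics reassemble the wide-field metric", {
  ph <- generatePhantom(phantomConfig(gridPx = c(250L, 250L), seed = 17,
                                      nDropoutPatches = 4L))
  m <- ph$truth@designedMetrics
  wide <- m[m$region == "wide", ]
  blocks <- m[grepl("^block_", m$region), ]
  for (v in c("TPD_pct", "CPD_pct", "LVD_pct", "CDD_pct")) {
    reassembled <- sum(blocks[[v]] * blocks$valid_area_mm2) /
      sum(blocks$valid_area_mm2)
    expect_equal(reassembled, wide[[v]], tolerance = 1e-6)
  }
  # central/annulus split reassembles too (dropout straddles the boundary)
  ca <- m[m$region %in% c("central6", "annulus"), ]
  for (v in c("TPD_pct", "CDD_pct")) {
    reassembled <- sum(ca[[v]] * ca$valid_area_mm2) / sum(ca$valid_area_mm2)
    expect_equal(reassembled, wide[[v]], tolerance = 1e-6)
  }
})

test_that("TPD = CPD + LVD holds on every record", {
  ph <- generatePhantom(phantomConfig(gridPx = c(250L, 250L), seed = 19,
                                      nDropoutPatches = 3L))
  m <- ph$truth@designedMetrics
  expect_true(all(abs(m$TPD_pct - m$CPD_pct - m$LVD_pct) < 1e-6))
  expect_true(all(m$CDD_pct <= 100 - m$TPD_pct + 1e-6))
})

test_that("block heatmap is zero on identical groups and local to a change", {
  ph <- generatePhantom(phantomConfig(gridPx = c(120L, 120L), seed = 23))
  m <- ph$truth@designedMetrics
  m$group <- "A"
  m2 <- m; m2$group <- "B"
  hm0 <- blockHeatmap(rbind(m, m2), "B", "A")
  expect_true(all(abs(hm0) < 1e-12))
  m3 <- m2
  m3$CPD_pct[m3$region == "block_2_3"] <- m3$CPD_pct[m3$region == "block_2_3"] / 2
  hm <- blockHeatmap(rbind(m, m3), "B", "A")
  expect_equal(hm[3, 4], -0.5, tolerance = 1e-12)
  expect_true(all(abs(hm[-(3 + (4 - 1) * 5)]) < 1e-12))
})
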