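test_that("the same seed reproduces every output bit for bit", {
  cfg <- phantomConfig(gridPx = c(120L, 120L), seed = 5, nDropoutPatches = 2L,
                       lowSignalPatches = cbind(2, 2, 1))
  a <- generatePhantom(cfg); b <- generatePhantom(cfg)
  expect_identical(pixels(a$angiogram), pixels(b$angiogram))
  expect_identical(pixels(a$structural), pixels(b$structural))
  expect_identical(pixels(a$truth@dropoutTruth), pixels(b$truth@dropoutTruth))
  expect_identical(a$truth@designedMetrics, b$truth@designedMetrics)
})

test_that("no dropout patches means near-zero designed CDD", {
  ph <- generatePhantom(phantomConfig(seed = 11))
  cdd <- ph$truth@designedMetrics$CDD_pct[1]
  expect_lt(cdd, 1.5)   # small intercapillary cells stay below the cutoff
})

test_that("the realized capillary fill fraction matches the target", {
  for (s in c(13, 14)) {
    ph <- generatePhantom(phantomConfig(seed = s,
                                        capillaryFillFraction = 0.55))
    frac <- mean(pixels(ph$truth@capillaryTruth)[!pixels(ph$truth@lvTruth)])
    expect_lt(abs(frac - 0.55), 0.02)
  }
})

test_that("truth masks are mutually consistent", {
  ph <- generatePhantom(phantomConfig(gridPx = c(200L, 200L), seed = 8,
                                      nDropoutPatches = 3L))
  lv <- pixels(ph$truth@lvTruth); cap <- pixels(ph$truth@capillaryTruth)
  expect_false(any(lv & cap))
  expect_false(any(pixels(ph$truth@dropoutTruth) & (lv | cap)))
})

test_that("an infeasible fill fraction is a configuration error", {
  expect_error(phantomConfig(capillaryFillFraction = 1.3), "\\[0, 1\\]")
})

test_that("cohort eyes within a subject are correlated via the fill effect", {
  cfgs <- list(g = phantomConfig(gridPx = c(64L, 64L)))
  co <- generateCohort(cfgs, nSubjects = 30L, seed = 42,
                       subjectSdFill = 0.05)
  wide <- co$truthMetrics[co$truthMetrics$region == "wide", ]
  e1 <- wide$TPD_pct[grepl("_e1$", wide$eye_id)]
  e2 <- wide$TPD_pct[grepl("_e2$", wide$eye_id)]
  expect_gt(cor(e1, e2), 0)
})

test_that("monotone dropout severity yields monotone designed metrics", {
  mkCfg <- function(n) phantomConfig(gridPx = c(200L, 200L),
                                     nDropoutPatches = n,
                                     dropoutRadiusRangeMM = c(0.8, 1.2))
  cfgs <- list(control = mkCfg(0L), noDR = mkCfg(2L), mildNPDR = mkCfg(6L),
               modsevNPDR = mkCfg(12L))
  co <- generateCohort(cfgs, nSubjects = 2L, seed = 7, subjectSdFill = 0)
  wide <- co$truthMetrics[co$truthMetrics$region == "wide", ]
  cdd <- tapply(wide$CDD_pct, wide$group, mean)[names(cfgs)]
  cpd <- tapply(wide$CPD_pct, wide$group, mean)[names(cfgs)]
  expect_true(all(diff(cdd) > 0))
  expect_true(all(diff(cpd) < 0))
  expect_error(generateCohort(cfgs, nSubjects = 1L, seed = 1), "2 subjects")
})

test_that("eccentricity bias pushes designed dropout into the annulus", {
  cdd <- sapply(3:5, function(s) {
    ph <- generatePhantom(phantomConfig(seed = s, nDropoutPatches = 8L,
                                        eccentricityBias = 4))
    m <- ph$truth@designedMetrics
    c(m$CDD_pct[m$region == "annulus"], m$CDD_pct[m$region == "central6"])
  })
  expect_gt(mean(cdd[1, ]), mean(cdd[2, ]))
})
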