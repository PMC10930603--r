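# The synthetic-data generator: determinism, ground-truth consistency, and
# controllable dynamics.

test_that("identical config and seed give bit-identical output", {
  cfg <- smallConfig(noiseSd = 2, bleedAlpha = 0.1, drift = 1,
                     backgroundLevel = 5)
  a <- generateTimelapse(cfg)
  b <- generateTimelapse(cfg)
  expect_identical(a$stack@data, b$stack@data)
  expect_identical(a$truth$mgVox, b$truth$mgVox)
  f1 <- generateFixedSection(cfg)
  f2 <- generateFixedSection(cfg)
  expect_identical(f1$image@data, f2$image@data)
})

test_that("zero turnover, drift, and noise freeze the microglia masks", {
  g <- generateTimelapse(smallConfig(processTurnover = 0))
  for (ly in c("ML", "PCL"))
    for (t in 2:6)
      expect_identical(g$truth$mgProj[[ly]][[t]], g$truth$mgProj[[ly]][[1]])
  # emitted frames are identical too
  expect_identical(g$stack@data[1, , 1, , ], g$stack@data[4, , 1, , ])
})

test_that("zero bleed leaves the microglia channel free of Purkinje signal", {
  g <- generateTimelapse(smallConfig(bleedAlpha = 0))
  s <- smallConfig()@imageShape
  pkOnly <- array(FALSE, dim = unname(s[c("y", "x", "z")]))
  pkOnly[g$truth$pkVox] <- TRUE
  pkOnly[g$truth$mgVox[[1]]] <- FALSE
  mg <- aperm(getFrame(g$stack, 1, "microglia"), c(2, 3, 1))  # (y,x,z)
  expect_equal(max(mg[pkOnly]), 0)
})

test_that("turnover parameter is recovered by direct pixel classification", {
  g <- cleanTimelapse()   # processTurnover 0.1
  for (ly in c("ML", "PCL"))
    expect_equal(truthMotility(g$truth, ly), 0.1, tolerance = 0.2)
  # tolerance 0.2 relative ~ +/- 0.02 absolute
})

test_that("thresholding the noise-free image reproduces ground truth", {
  g <- cleanTimelapse()
  s <- smallConfig()@imageShape
  thr <- g$truth$params$emissionThreshold
  for (t in c(1, 4)) {
    mgTruth <- array(FALSE, dim = unname(s[c("y", "x", "z")]))
    mgTruth[g$truth$mgVox[[t]]] <- TRUE
    mg <- getFrame(g$stack, t, "microglia")
    expect_identical(unname(mg >= thr["microglia"]), aperm(mgTruth, c(3, 1, 2)))
    pkTruth <- array(FALSE, dim = unname(s[c("y", "x", "z")]))
    pkTruth[g$truth$pkVox] <- TRUE
    pk <- getFrame(g$stack, t, "purkinje")
    expect_identical(unname(pk >= thr["purkinje"]), aperm(pkTruth, c(3, 1, 2)))
  }
})

test_that("degenerate image shapes are rejected", {
  expect_error(synthConfig(imageShape = c(y = 8L, x = 64L, z = 24L)),
               "degenerate")
})

test_that("fixed sections place somas at the configured density", {
  cfg <- synthConfig(imageShape = c(y = 256L, x = 384L, z = 16L),
                     somaPlacement = "poisson", noiseSd = 0, seed = 7L)
  gen <- generateFixedSection(cfg)
  glTruth <- gen$truth$mgSomas[gen$truth$mgSomas$layer == "GL", ]
  areaGL <- roiAreaUm2(gen$rois$GL)
  expectN <- 2e-4 * areaGL
  # Poisson count within 4 sd (edge-trimmed cells allowed to reduce it)
  expect_gt(nrow(glTruth), expectN - 4 * sqrt(expectN) - 2)
  expect_lt(nrow(glTruth), expectN + 4 * sqrt(expectN))
  # all truth somas lie inside their layer polygon
  inGL <- pointsInPolygon(cbind(glTruth$x, glTruth$y), gen$rois$GL@polygon)
  expect_true(all(inGL))
})

test_that("Purkinje soma count tracks the configured spacing", {
  cfg <- synthConfig(imageShape = c(y = 256L, x = 768L, z = 16L),
                     pclSomaSpacingUm = 100, noiseSd = 0, seed = 8L)
  gen <- generateFixedSection(cfg)
  L <- gen$truth$params$pathLengthUm
  n <- nrow(gen$truth$pkSomas)
  expect_equal(n, L / 100, tolerance = 2.5 / n)  # +/- ~2 somas
})

test_that("a multiplicative group effect is realized exactly in truth", {
  cfg <- synthConfig(imageShape = c(y = 128L, x = 256L, z = 16L),
                     groupEffects = list(
                       ethanol = c(pclLinearDensity = 0.92),
                       ethanol.F = c(pclLinearDensity = 0.95)),
                     seed = 9L)
  sal <- generateFixedSection(cfg, group = c(treatment = "saline", sex = "M"))
  eth <- generateFixedSection(cfg, group = c(treatment = "ethanol", sex = "M"))
  ethF <- generateFixedSection(cfg, group = c(treatment = "ethanol", sex = "F"))
  expect_equal(eth$truth$params$pclLinearDensityUm /
                 sal$truth$params$pclLinearDensityUm, 0.92)
  # sex-specific key multiplies on top of the treatment key
  expect_equal(ethF$truth$params$pclLinearDensityUm /
                 sal$truth$params$pclLinearDensityUm, 0.92 * 0.95)
})

test_that("injury series has analytic convergence ground truth", {
  cfg <- smallConfig(imageShape = c(y = 96L, x = 96L, z = 16L),
                     nTimepoints = 12L)
  still <- generateInjurySeries(cfg, ratePx = 0)
  expect_equal(still$truth$proximity, rep(1, 12))
  inj <- generateInjurySeries(cfg, coreRadiusPx = 10, frontRadiusPx = 30,
                              ratePx = 2)
  # circle-area oracle: radii shrink 30, 28, ..., floored at the core
  radii <- pmax(10, 30 - 2 * (0:11))
  circleArea <- function(r) {
    ang <- seq(0, 2 * pi, length.out = 73)[-73]
    oracleShoelace(cbind(r * cos(ang), r * sin(ang)))
  }
  want <- (vapply(radii, circleArea, numeric(1)) - circleArea(10)) /
    (circleArea(30) - circleArea(10))
  expect_equal(inj$truth$proximity, want)
  # fast enough to reach the core: proximity 0 afterwards
  fast <- generateInjurySeries(cfg, coreRadiusPx = 10, frontRadiusPx = 30,
                               ratePx = 4)
  expect_true(all(fast$truth$proximity[6:12] == 0))
  expect_error(generateInjurySeries(cfg, frontRadiusPx = 60), "inside")
})

test_that("occupancy regions realize the target fraction exactly", {
  dims <- c(y = 64L, x = 64L, z = 10L)
  for (q in c(0.005, 0.02, 0.25)) {
    reg <- generateOccupancyRegion(dims, q, noiseSd = 0, seed = 3L)
    expect_equal(sum(reg$mask), round(q * prod(dims)))
  }
})
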