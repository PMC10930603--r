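# Threshold + morphology segmentation surrogates.

test_that("binarization applies threshold and size exclusion", {
  expect_equal(maskSize(binarizeObjects(matrix(0, 10, 10), 1)), 0)
  img <- matrix(0, 100, 100)
  img[2:6, 2] <- 10                       # size 5
  img[20:29, 20:24] <- 10                 # size 50
  img[40:89, 40:89] <- 10                 # size 2500
  bm <- binarizeObjects(img, 5, minSize = 10, maxSize = 1000)
  lab <- labelComponents(bm)
  expect_equal(attr(lab, "max"), 1L)
  expect_equal(maskSize(bm), 50)
  # no filtering, threshold at the minimum: everything is foreground
  full <- binarizeObjects(img, min(img))
  expect_equal(maskSize(full), length(img))
})

test_that("raising the threshold never adds foreground", {
  set.seed(6)
  img <- matrix(runif(400, 0, 10), 20, 20)
  for (i in 1:10) {
    t1 <- runif(1, 0, 8); t2 <- t1 + runif(1, 0, 2)
    m1 <- maskArray(binarizeObjects(img, t1))
    m2 <- maskArray(binarizeObjects(img, t2))
    expect_true(all(m1 | !m2))   # m2 subset of m1
  }
})

test_that("somas are detected at their centroids", {
  img <- array(FALSE, dim = c(80, 100, 9))
  for (dz in -3:3) {
    r <- sqrt(16 - dz^2 * 16 / 9)
    px <- gliaquant:::.discPixels(40, 60, r, 80, 100)
    img[cbind(px, 5 + dz)] <- TRUE
  }
  s1 <- detectSomas(img, somaMinSize = 20)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$y, 40, tolerance = 0.5 / 40)
  expect_equal(s1$x, 60, tolerance = 0.5 / 60)
  # two disjoint spheres -> two somas
  img[cbind(gliaquant:::.discPixels(15, 15, 4, 80, 100), 5)] <- TRUE
  s2 <- detectSomas(img, somaMinSize = 20)
  expect_equal(nrow(s2), 2)
})

test_that("grid-placed somas are recovered with near-perfect precision/recall", {
  cfg <- synthConfig(imageShape = c(y = 512L, x = 512L, z = 16L),
                     microgliaDensity = c(ML = 4e-4, PCL = 4e-4, GL = 4e-4,
                                          WM = 4e-4),
                     somaPlacement = "grid", noiseSd = 2, seed = 12L)
  gen <- generateFixedSection(cfg)
  truthXY <- cbind(gen$truth$mgSomas$y, gen$truth$mgSomas$x)
  expect_gte(nrow(truthXY), 80)
  proj <- maxProject(getFrame(gen$image, 1, "microglia"), zAxis = 1)
  mask <- binarizeObjects(proj, 50, minSize = 5)
  det <- detectSomas(mask, somaMinSize = 12, somaMaxSize = 200,
                     openRadius = 2)
  # match detections to truth within 4 px
  D <- outer(det$y, truthXY[, 1], `-`)^2 + outer(det$x, truthXY[, 2], `-`)^2
  matched <- apply(D, 1, min) <= 16
  recallHit <- apply(D, 2, min) <= 16
  expect_gte(mean(matched), 0.99)      # precision
  expect_gte(mean(recallHit), 0.99)    # recall
})

test_that("soma/process split partitions the mask exactly", {
  m <- matrix(FALSE, 60, 60)
  m[cbind(gliaquant:::.discPixels(30, 30, 6, 60, 60))] <- TRUE
  m[30, 37:55] <- TRUE
  parts <- classifySubcomponents(BinaryMask(m), rSoma = 3)
  sm <- maskArray(parts$soma); pm <- maskArray(parts$process)
  expect_identical(sm | pm, m)
  expect_false(any(sm & pm))
  expect_true(all(pm[30, 45:55]))
  # process-free blob of diameter ~2 r_soma (open by construction): all soma
  seed <- matrix(FALSE, 40, 40)
  seed[cbind(gliaquant:::.discPixels(20, 20, 3, 40, 40))] <- TRUE
  d <- gliaquant:::.dilateDisc(seed, 3)
  pd <- classifySubcomponents(BinaryMask(d), rSoma = 3)
  expect_equal(maskSize(pd$process), 0)
  # 1-px line only: all process (with a warning)
  l <- matrix(FALSE, 40, 40); l[20, 5:35] <- TRUE
  expect_warning(pl <- classifySubcomponents(BinaryMask(l), rSoma = 3),
                 "process")
  expect_equal(maskSize(pl$soma), 0)
  expect_identical(maskArray(pl$process), l)
  expect_error(classifySubcomponents(BinaryMask(matrix(FALSE, 5, 5))),
               "empty")
})

test_that("branch points are found on skeletonized Purkinje masks", {
  line <- matrix(FALSE, 50, 50); line[10:40, 25] <- TRUE
  r1 <- classifyPurkinjeComponents(BinaryMask(line), "ML")
  expect_equal(r1$nBranchPoints, 0)
  # Y shape: one bifurcation
  y <- matrix(FALSE, 60, 60)
  y[30:50, 30] <- TRUE
  for (k in 0:14) { y[29 - k, 30 - k] <- TRUE; y[29 - k, 30 + k] <- TRUE }
  r2 <- classifyPurkinjeComponents(BinaryMask(y), "ML")
  expect_equal(r2$nBranchPoints, 1)
  # dendrite + branch masks partition the input
  un <- maskArray(r2$dendrite) | maskArray(r2$branch)
  expect_identical(un, y)
  expect_false(any(maskArray(r2$dendrite) & maskArray(r2$branch)))
})

test_that("generator arbors yield the constructed number of bifurcations", {
  # fixed-section Purkinje trunks fork exactly once per soma (2-D projection)
  cfg <- synthConfig(imageShape = c(y = 128L, x = 256L, z = 16L),
                     pclSomaSpacingUm = 60, noiseSd = 0, seed = 13L)
  gen <- generateFixedSection(cfg)
  nSomas <- nrow(gen$truth$pkSomas)
  proj <- maxProject(getFrame(gen$image, 1, "purkinje"), zAxis = 1)
  mlMask <- maskArray(binarizeObjects(proj, 50)) &
    gliaquant:::.polygonMask(gen$rois$ML_PCL@polygon, 128, 256)
  res <- classifyPurkinjeComponents(BinaryMask(mlMask), "ML")
  # somas + axon crossings add junctions; require the right order of
  # magnitude rather than exact equality (+/- 1 per arbor)
  expect_gte(res$nBranchPoints, nSomas - 1)
})

test_that("PCL mode delegates to soma detection", {
  m <- array(FALSE, dim = c(40, 40, 5))
  m[cbind(gliaquant:::.discPixels(20, 20, 5, 40, 40), 3)] <- TRUE
  out <- classifyPurkinjeComponents(BinaryMask(m), "PCL", somaMinSize = 10)
  expect_equal(nrow(out$somas), 1)
})
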