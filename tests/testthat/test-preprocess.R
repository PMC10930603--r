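# Blinding, drift correction, bleed-through, PCA denoising, layer splits,
# and projections.

test_that("blinding is a deterministic bijection that round-trips", {
  paths <- sprintf("animal_%d.tif", 1:4)
  k1 <- blindDataset(paths, seed = 7)
  k2 <- blindDataset(paths, seed = 7)
  expect_identical(k1, k2)
  expect_setequal(k1$original, paths)
  expect_equal(anyDuplicated(k1$blindId), 0L)
  k3 <- blindDataset(paths, seed = 8)
  expect_false(identical(k1$original, k3$original))
  expect_error(blindDataset(c("a", "a"), 1), "duplicate")
  keyFile <- tempfile(fileext = ".csv")
  blindDataset(paths, 7, keyFile)
  expect_identical(read.csv(keyFile, stringsAsFactors = FALSE)$original,
                   k1$original)
})

test_that("drift correction recovers injected integer offsets exactly", {
  g0 <- generateTimelapse(smallConfig(noiseSd = 1, backgroundLevel = 5))
  dc0 <- correctDrift(g0$stack)
  expect_true(all(dc0$drift == 0))
  dr <- matrix(0L, 6, 2)
  dr[5, ] <- c(3L, -2L); dr[3, ] <- c(-1L, 2L)
  g <- generateTimelapse(smallConfig(drift = dr, noiseSd = 1,
                                     backgroundLevel = 5))
  dc <- correctDrift(g$stack)
  expect_identical(unname(dc$drift), unname(dr))
  # idempotence: registering the registered stack gives zero offsets
  dc2 <- correctDrift(dc$stack)
  expect_true(all(dc2$drift == 0))
})

test_that("registering a stack against itself is the identity", {
  g <- generateTimelapse(smallConfig(noiseSd = 2, backgroundLevel = 5))
  st <- g$stack
  st@data <- st@data[c(1, 1, 1), , , , , drop = FALSE]  # 3 copies of t=1
  dc <- correctDrift(st)
  expect_true(all(dc$drift == 0))
  expect_identical(dc$stack@data, st@data)
})

test_that("bleed-through alpha is recovered from Purkinje-only pixels", {
  s <- c(y = 64L, x = 64L, z = 24L)
  pkOnlyOf <- function(g) {
    v <- array(FALSE, dim = unname(s))
    v[g$truth$pkVox] <- TRUE
    v[g$truth$mgVox[[1]]] <- FALSE
    aperm(v, c(3, 1, 2))
  }
  g0 <- generateTimelapse(smallConfig(bleedAlpha = 0, noiseSd = 0.5,
                                      backgroundLevel = 5))
  a0 <- estimateBleedthrough(g0$stack, pkOnlyOf(g0))$alpha
  expect_lte(a0, 0.01)
  g2 <- generateTimelapse(smallConfig(bleedAlpha = 0.2, noiseSd = 0.5,
                                      backgroundLevel = 5))
  a2 <- estimateBleedthrough(g2$stack, pkOnlyOf(g2))$alpha
  expect_equal(a2, 0.2, tolerance = 0.05)  # +/- 0.01 absolute
  expect_error(estimateBleedthrough(g2$stack, logical(0)), "empty")
})

test_that("alpha is a slope: doubling Purkinje brightness leaves it fixed", {
  set.seed(11)
  pk <- matrix(runif(400, 50, 150), 20, 20)
  mg <- 5 + 0.2 * pk + rnorm(400, 0, 0.5)
  mk <- function(pkf) {
    d <- array(0, dim = c(2, 1, 2, 20, 20))
    d[1, 1, 1, , ] <- mg; d[1, 1, 2, , ] <- pkf
    d[2, 1, , , ] <- d[1, 1, , , ]
    TimelapseStack(d)
  }
  sel <- array(TRUE, dim = c(1, 20, 20))
  a1 <- estimateBleedthrough(mk(pk), sel)$alpha
  mg2 <- 5 + 0.2 * (2 * pk) + rnorm(400, 0, 0.5)
  d2 <- array(0, dim = c(2, 1, 2, 20, 20))
  d2[1, 1, 1, , ] <- mg2; d2[1, 1, 2, , ] <- 2 * pk
  d2[2, 1, , , ] <- d2[1, 1, , , ]
  a2 <- estimateBleedthrough(TimelapseStack(d2), sel)$alpha
  expect_equal(a1, 0.2, tolerance = 0.02)
  expect_equal(a2, 0.2, tolerance = 0.02)
})

test_that("bleed subtraction removes Purkinje residue and never goes negative", {
  s <- c(y = 64L, x = 64L, z = 24L)
  g <- generateTimelapse(smallConfig(bleedAlpha = 0.2, noiseSd = 0.5,
                                     backgroundLevel = 5))
  v <- array(FALSE, dim = unname(s))
  v[g$truth$pkVox] <- TRUE
  v[g$truth$mgVox[[1]]] <- FALSE
  pkOnly <- aperm(v, c(3, 1, 2))
  alpha <- estimateBleedthrough(g$stack, pkOnly)$alpha
  out <- subtractBleedthrough(g$stack, alpha)
  resid <- getFrame(out, 1, "microglia")[pkOnly]
  expect_lte(mean(resid), 0.5)        # <= noise sd
  expect_gte(min(out@data), 0)
  # alpha = 0: microglia channel changes only by the background offset
  out0 <- subtractBleedthrough(g$stack, 0)
  f0 <- getFrame(g$stack, 1, "microglia")
  f1 <- getFrame(out0, 1, "microglia")
  offs <- (f0 - f1)[f1 > 0]
  expect_lte(diff(range(offs)), 1e-9)  # constant shift where unclipped
})

test_that("temporal PCA reconstructs exactly at full rank and denoises", {
  g <- generateTimelapse(smallConfig(noiseSd = 0, backgroundLevel = 0,
                                     processTurnover = 0))
  # constant stack: k = 1 leaves it unchanged
  p1 <- pcaDenoise(g$stack, 1)
  expect_equal(p1@data, g$stack@data, tolerance = 1e-8)
  gn <- generateTimelapse(smallConfig(noiseSd = 4, backgroundLevel = 0,
                                      processTurnover = 0))
  # full rank: identity
  pAll <- pcaDenoise(gn$stack, 6)
  expect_equal(pAll@data, gn$stack@data, tolerance = 1e-6)
  # static scene + noise: k = 1 must beat the raw input against truth
  p2 <- pcaDenoise(gn$stack, 1)
  mseIn <- mean((gn$stack@data[, , 1, , ] - g$stack@data[, , 1, , ])^2)
  mseOut <- mean((p2@data[, , 1, , ] - g$stack@data[, , 1, , ])^2)
  expect_lt(mseOut, mseIn)
  expect_warning(pcaDenoise(gn$stack, 7), "timepoints")
})

test_that("layer splits use half-open intervals of equal depth", {
  d <- array(0, dim = c(2, 20, 1, 8, 8))
  for (z in 1:20) d[, z, 1, , ] <- z
  st <- TimelapseStack(d, channels = "microglia")
  sp <- splitLayers(st, pclStartZ = 12, nSlices = 5)
  expect_equal(unique(as.vector(sp$ML@data[1, , 1, , ])), 7:11)
  expect_equal(unique(as.vector(sp$PCL@data[1, , 1, , ])), 12:16)
  expect_equal(dim(sp$ML@data)[2], dim(sp$PCL@data)[2])
  expect_error(splitLayers(st, 18, 5), "out of bounds")
  expect_error(splitLayers(st, 4, 5), "out of bounds")
})

test_that("layer split captures the PCL soma monolayer", {
  g <- cleanTimelapse()
  pclZ <- g$truth$pclStartZ
  sp <- splitLayers(g$stack, pclZ, 8)
  # Purkinje soma voxels: fraction inside the PCL substack z-range
  s <- c(64L, 64L, 24L)
  zOf <- (g$truth$pkVox - 1) %/% (s[1] * s[2]) + 1
  somaZ <- zOf[zOf >= pclZ]   # soma monolayer sits below the boundary
  expect_gte(mean(somaZ >= pclZ & somaZ < pclZ + 8), 0.95)
})

test_that("maximum projection equals the per-pixel brute-force maximum", {
  m <- array(0, dim = c(1, 8, 8))
  m[1, 2, 3] <- 5
  expect_equal(maxProject(m), m[1, , ])
  set.seed(5)
  a <- array(runif(6 * 10 * 10), dim = c(6, 10, 10))  # (z, y, x)
  got <- maxProject(a)
  want <- matrix(0, 10, 10)
  for (y in 1:10) for (x in 1:10) want[y, x] <- max(a[, y, x])
  expect_equal(got, want)
  # two disjoint disks on separate planes project to their union
  d <- array(FALSE, dim = c(8, 8, 2))
  d[2:3, 2:3, 1] <- TRUE; d[6:7, 6:7, 2] <- TRUE
  expect_equal(maxProject(d), d[, , 1] | d[, , 2])
})
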