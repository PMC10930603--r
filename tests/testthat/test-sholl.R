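# Sholl ring-intersection counting and the change-point curve model.

test_that("intersection counts follow arc counting on drawn masks", {
  # straight 11 um process, 2 px wide: one crossing out to r = 10, none past
  m <- matrix(FALSE, 64, 64)
  m[32:33, 32:42] <- TRUE
  sc <- shollIntersections(m, c(32, 32), 2, 14)
  expect_equal(sc$intersections, c(1, 1, 1, 1, 1, 0, 0))
  # empty mask: all zero
  e <- shollIntersections(matrix(FALSE, 30, 30), c(15, 15), 2, 10)
  expect_true(all(e$intersections == 0))
  # Y bifurcating at r = 5: 1 crossing inside, 2 outside (arms 2 px wide)
  y <- matrix(FALSE, 64, 64)
  y[32:33, 32:37] <- TRUE
  for (k in 0:9) {
    y[32 - k + 0:1, 37 + k] <- TRUE
    y[32 + k + 0:1, 37 + k] <- TRUE
  }
  sy <- shollIntersections(y, c(32, 32), 2, 10)
  expect_equal(sy$intersections[1:2], c(1, 1))
  # at r = 6 the two arms have not yet separated by a full pixel
  expect_equal(sy$intersections[4:5], c(2, 2))
})

test_that("counts equal an independent run-length walk of each ring", {
  set.seed(31)
  for (i in 1:25) {
    m <- matrix(runif(48 * 48) < 0.3, 48, 48)
    cen <- c(sample(15:33, 1), sample(15:33, 1))
    got <- shollIntersections(m, cen, 2, 12)$intersections
    want <- vapply(seq(2, 12, 2), function(r) {
      ring <- gliaquant:::.rasterCircle(r)
      ys <- cen[1] + ring[, 2]; xs <- cen[2] + ring[, 1]
      ok <- ys >= 1 & ys <= 48 & xs >= 1 & xs <= 48
      v <- logical(nrow(ring)); v[ok] <- m[cbind(ys[ok], xs[ok])]
      if (!any(v)) return(0L)
      if (all(v)) return(1L)
      # rle-based run count with circular join, written independently
      runs <- rle(v)
      n <- sum(runs$values)
      if (runs$values[1] && runs$values[length(runs$values)]) n <- n - 1L
      as.integer(n)
    }, integer(1))
    expect_equal(got, want)
  }
})

test_that("the fitted curve peaks at the branch maximum exp(tau)", {
  p <- list(tau = 2.2, alpha1 = 0.12, alpha2 = -0.07, gamma = 24)
  expect_equal(predictSholl(p, 24), exp(2.2))
  r <- seq(2, 70, 2)
  expect_true(all(predictSholl(p, r) <= exp(2.2) + 1e-12))
})

test_that("profile fit recovers parameters from exact model data", {
  radii <- seq(2, 60, 2)
  lam <- predictSholl(list(tau = 2, alpha1 = 0.1, alpha2 = -0.08,
                           gamma = 20), radii)
  f <- fitShollCurve(data.frame(radiusUm = radii, intersections = round(lam)))
  expect_lte(abs(f$gamma - 20), 2)   # within one ring interval
  expect_equal(f$tau, 2, tolerance = 0.05)
  expect_equal(f$alpha1, 0.1, tolerance = 0.15)
  expect_equal(f$alpha2, -0.08, tolerance = 0.15)
  # degenerate curve: fewer than two nonzero rings
  expect_warning(out <- fitShollCurve(data.frame(
    radiusUm = radii, intersections = c(3, rep(0, 29)))), "excluded")
  expect_null(out)
})

test_that("simulated hierarchies honour their design and effects", {
  sim <- simulateShollCurves(3, 2, data.frame(treatment = c("saline",
                                                            "ethanol")),
                             treatmentEffects = c(tau = -0.5, alpha1 = 0,
                                                  alpha2 = 0, gamma = 0),
                             seed = 5)
  expect_equal(length(unique(sim$curves$cell)), 12)
  expect_equal(nrow(sim$animalParams), 4)
  counts <- sim$curves$intersections
  expect_true(all(counts >= 0) && all(counts == round(counts)))
  # determinism
  sim2 <- simulateShollCurves(3, 2, data.frame(treatment = c("saline",
                                                             "ethanol")),
                              treatmentEffects = c(tau = -0.5, alpha1 = 0,
                                                   alpha2 = 0, gamma = 0),
                              seed = 5)
  expect_identical(sim$curves, sim2$curves)
})

test_that("hierarchical fit recovers a treatment effect on tau", {
  sim <- simulateShollCurves(10, 5, data.frame(treatment = c("saline",
                                                             "ethanol")),
                             treatmentEffects = c(tau = -0.5, alpha1 = 0,
                                                  alpha2 = 0, gamma = 0),
                             seed = 3)
  fit <- fitShollModel(sim$curves, nChains = 2, nAdapt = 600, nBurn = 600,
                       nSample = 1200, seed = 1)
  eff <- fit@effects
  tauEff <- eff$mean[grep("^tau:", eff$coefficient)]
  expect_equal(tauEff, -0.5, tolerance = 0.3)  # +/- 0.15 absolute
  # null parameters: credible intervals cover zero
  for (par in c("alpha1", "alpha2")) {
    row <- eff[grep(paste0("^", par, ":"), eff$coefficient), ]
    expect_lte(row$lower, 0)
    expect_gte(row$upper, 0)
  }
})

test_that("equal slopes flag a weakly identified change-point", {
  sim <- simulateShollCurves(4, 3, data.frame(treatment = "saline"),
                             groupMeans = list(tau = 2, alpha1 = -0.05,
                                               alpha2 = -0.05, gamma = 30),
                             seed = 9)
  fit <- fitShollModel(sim$curves, nChains = 2, nAdapt = 300, nBurn = 300,
                       nSample = 600, seed = 2)
  expect_s4_class(fit, "ShollFit")
  expect_true(fit@gammaWide)
})
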