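# Sholl analysis: ring-intersection counting on binary masks and a
# hierarchical Bayesian change-point model of the Sholl curve.
#
# The curve model is piecewise log-linear and continuous at the
# change-point gamma:
#   E[I(r)] = exp(tau + alpha1 * (r - gamma))  for r <= gamma
#   E[I(r)] = exp(tau + alpha2 * (r - gamma))  for r >  gamma
# so the branch maximum exp(tau) is attained at r = gamma. Counts are
# modeled as Poisson.

#' Sholl ring-intersection counts
#'
#' Counts, for concentric rings around the soma center, the number of
#' foreground arcs along each rasterized (Bresenham) circle: maximal runs
#' of foreground pixels on the angularly ordered circle, joined circularly
#' (a fully foreground ring counts as one arc).
#'
#' @param mask 2-D \linkS4class{BinaryMask} or logical matrix.
#' @param somaCenter numeric c(y, x) in pixel coordinates (inside the mask).
#' @param ringIntervalUm ring spacing in micrometers (default 2).
#' @param maxRadiusUm largest ring radius in micrometers (default 70 for
#'   in-vivo fields; use 100 for fixed tissue).
#' @param pixelSizeUm in-plane calibration; taken from the BinaryMask when
#'   available.
#' @return data.frame(radiusUm, intersections).
#' @export
shollIntersections <- function(mask, somaCenter, ringIntervalUm = 2,
                               maxRadiusUm = 70, pixelSizeUm = NULL) {
  m <- if (is(mask, "BinaryMask")) maskArray(mask) else mask
  if (is.null(pixelSizeUm))
    pixelSizeUm <- if (is(mask, "BinaryMask")) mask@pixelSizeUm else 1
  ny <- nrow(m); nx <- ncol(m)
  yc <- somaCenter[1]; xc <- somaCenter[2]
  if (yc < 1 || yc > ny || xc < 1 || xc > nx)
    stop("somaCenter outside mask bounds")
  radii <- seq(ringIntervalUm, maxRadiusUm, by = ringIntervalUm)
  counts <- integer(length(radii))
  for (i in seq_along(radii)) {
    ring <- .rasterCircle(radii[i] / pixelSizeUm)
    ys <- round(yc) + ring[, 2]
    xs <- round(xc) + ring[, 1]
    ok <- ys >= 1 & ys <= ny & xs >= 1 & xs <= nx
    v <- logical(nrow(ring))
    v[ok] <- m[cbind(ys[ok], xs[ok])]
    if (!any(v)) { counts[i] <- 0L; next }
    if (all(v)) { counts[i] <- 1L; next }
    counts[i] <- sum(v & !c(v[length(v)], v[-length(v)]))
  }
  data.frame(radiusUm = radii, intersections = counts)
}

#' Expected Sholl curve of the change-point model
#'
#' @param params named list or vector with tau, alpha1, alpha2, gamma.
#' @param radii radii (um) at which to evaluate.
#' @return Expected intersection counts exp(tau + alpha * (r - gamma)).
#' @export
predictSholl <- function(params, radii) {
  p <- as.list(params)
  slope <- ifelse(radii <= p$gamma, p$alpha1, p$alpha2)
  exp(p$tau + slope * (radii - p$gamma))
}

#' Maximum-likelihood change-point fit of a single Sholl curve
#'
#' Profiles the change-point gamma over the observed radius grid; for each
#' candidate gamma the remaining parameters are a Poisson GLM
#' log E[I] = tau + alpha1 * min(r - gamma, 0) + alpha2 * max(r - gamma, 0).
#' The gamma with the smallest deviance wins. When alpha1 and alpha2 are
#' indistinguishable, gamma is weakly identified; the profile deviance is
#' returned so that flat profiles can be recognized.
#'
#' @param curve data.frame(radiusUm, intersections) from
#'   \code{\link{shollIntersections}}.
#' @return list(tau, alpha1, alpha2, gamma, deviance, profile =
#'   data.frame(gamma, deviance)); NULL if fewer than two rings have
#'   nonzero counts.
#' @export
fitShollCurve <- function(curve) {
  r <- curve$radiusUm; y <- curve$intersections
  if (sum(y > 0) < 2) {
    warning("fewer than 2 rings with nonzero counts; curve excluded")
    return(NULL)
  }
  grid <- r[r > min(r) & r < max(r)]
  prof <- vapply(grid, function(g) {
    x1 <- pmin(r - g, 0); x2 <- pmax(r - g, 0)
    fit <- suppressWarnings(glm(y ~ x1 + x2, family = poisson()))
    fit$deviance
  }, numeric(1))
  g <- grid[which.min(prof)]
  x1 <- pmin(r - g, 0); x2 <- pmax(r - g, 0)
  fit <- suppressWarnings(glm(y ~ x1 + x2, family = poisson()))
  co <- coef(fit)
  list(tau = unname(co[1]), alpha1 = unname(co[2]), alpha2 = unname(co[3]),
       gamma = g, deviance = fit$deviance,
       profile = data.frame(gamma = grid, deviance = prof))
}

#' Simulate Sholl curves from the hierarchical change-point model
#'
#' Group-level parameter means (plus optional treatment effects) generate
#' animal-level then cell-level parameters by Gaussian perturbation, and
#' Poisson counts at the requested radii. Used for parameter-recovery and
#' calibration studies.
#'
#' @param nCellsPerAnimal,nAnimalsPerGroup,design sizes; design is a
#'   data.frame with one row per group and columns \code{treatment} and
#'   optionally \code{sex}.
#' @param groupMeans named list tau, alpha1, alpha2, gamma of control means.
#' @param treatmentEffects named numeric of additive effects applied to
#'   treated groups (on the same scales), default all 0.
#' @param sdAnimal,sdCell named numerics of between-animal and between-cell
#'   SDs per parameter.
#' @param radii radii (um) of the rings.
#' @param seed RNG seed.
#' @return list(curves = long data.frame(animal, cell, treatment, sex,
#'   radiusUm, intersections), cellParams, animalParams).
#' @export
simulateShollCurves <- function(nCellsPerAnimal, nAnimalsPerGroup, design,
    groupMeans = list(tau = 2, alpha1 = 0.10, alpha2 = -0.08, gamma = 20),
    treatmentEffects = c(tau = 0, alpha1 = 0, alpha2 = 0, gamma = 0),
    sdAnimal = c(tau = 0.15, alpha1 = 0.01, alpha2 = 0.008, gamma = 2),
    sdCell = c(tau = 0.2, alpha1 = 0.015, alpha2 = 0.01, gamma = 3),
    radii = seq(2, 60, by = 2), seed = 1L) {
  set.seed(seed)
  pars <- c("tau", "alpha1", "alpha2", "gamma")
  curves <- NULL; cellParams <- NULL; animalParams <- NULL
  aId <- 0
  for (g in seq_len(nrow(design))) {
    treated <- design$treatment[g] != design$treatment[1]
    mu <- unlist(groupMeans)[pars] +
      (if (treated) treatmentEffects[pars] else rep(0, 4))
    for (a in seq_len(nAnimalsPerGroup)) {
      aId <- aId + 1
      muA <- mu + rnorm(4, 0, sdAnimal[pars])
      animalParams <- rbind(animalParams,
        data.frame(animal = aId, treatment = design$treatment[g],
                   t(setNames(muA, pars))))
      for (cc in seq_len(nCellsPerAnimal)) {
        muC <- muA + rnorm(4, 0, sdCell[pars])
        muC["gamma"] <- min(max(muC["gamma"], min(radii) + 2),
                            max(radii) - 2)
        lam <- predictSholl(as.list(setNames(muC, pars)), radii)
        curves <- rbind(curves, data.frame(
          animal = aId, cell = paste0(aId, "_", cc),
          treatment = design$treatment[g],
          sex = if ("sex" %in% names(design)) design$sex[g] else "pooled",
          radiusUm = radii, intersections = rpois(length(radii), lam)))
        cellParams <- rbind(cellParams,
          data.frame(animal = aId, cell = paste0(aId, "_", cc),
                     t(setNames(muC, pars))))
      }
    }
  }
  list(curves = curves, cellParams = cellParams, animalParams = animalParams)
}

.shollJagsModel <- "
model {
  for (i in 1:N) {
    loglam[i] <- tau_c[cell[i]] +
      (step(gam_c[cell[i]] - r[i]) * a1_c[cell[i]] +
       (1 - step(gam_c[cell[i]] - r[i])) * a2_c[cell[i]]) *
      (r[i] - gam_c[cell[i]])
    y[i] ~ dpois(exp(loglam[i]))
  }
  for (c in 1:C) {
    tau_c[c] ~ dnorm(tau_a[cellAnimal[c]], prec_tau_c)
    a1_c[c]  ~ dnorm(a1_a[cellAnimal[c]],  prec_a1_c)
    a2_c[c]  ~ dnorm(a2_a[cellAnimal[c]],  prec_a2_c)
    gam_c[c] ~ dnorm(gam_a[cellAnimal[c]], prec_gam_c) T(rmin, rmax)
  }
  for (a in 1:A) {
    tau_a[a] ~ dnorm(inprod(X[a, ], beta_tau[]), prec_tau_a)
    a1_a[a]  ~ dnorm(inprod(X[a, ], beta_a1[]),  prec_a1_a)
    a2_a[a]  ~ dnorm(inprod(X[a, ], beta_a2[]),  prec_a2_a)
    gam_a[a] ~ dnorm(inprod(X[a, ], beta_gam[]), prec_gam_a)
  }
  beta_tau[1] ~ dnorm(0, 0.1)
  beta_a1[1]  ~ dnorm(0, 1)
  beta_a2[1]  ~ dnorm(0, 1)
  beta_gam[1] ~ dnorm(gmid, 0.001)
  for (p in 2:P) {
    beta_tau[p] ~ dnorm(0, 0.25)
    beta_a1[p]  ~ dnorm(0, 4)
    beta_a2[p]  ~ dnorm(0, 4)
    beta_gam[p] ~ dnorm(0, 0.01)
  }
  sd_tau_c ~ dunif(0, 2);   prec_tau_c <- pow(sd_tau_c, -2)
  sd_a1_c  ~ dunif(0, 0.5); prec_a1_c  <- pow(sd_a1_c, -2)
  sd_a2_c  ~ dunif(0, 0.5); prec_a2_c  <- pow(sd_a2_c, -2)
  sd_gam_c ~ dunif(0, 15);  prec_gam_c <- pow(sd_gam_c, -2)
  sd_tau_a ~ dunif(0, 2);   prec_tau_a <- pow(sd_tau_a, -2)
  sd_a1_a  ~ dunif(0, 0.5); prec_a1_a  <- pow(sd_a1_a, -2)
  sd_a2_a  ~ dunif(0, 0.5); prec_a2_a  <- pow(sd_a2_a, -2)
  sd_gam_a ~ dunif(0, 15);  prec_gam_a <- pow(sd_gam_a, -2)
}
"

#' ShollFit: posterior summaries of the hierarchical change-point model
#'
#' @slot summary data.frame of posterior mean and 95\% credible bounds for
#'   every monitored group-level coefficient.
#' @slot effects data.frame restricted to treatment / sex effect rows.
#' @slot rhat named numeric of split-Rhat values for the coefficients.
#' @slot converged logical, all Rhat < 1.05.
#' @slot gammaWide logical, flat change-point: the posterior SD of the
#'   gamma intercept exceeds a quarter of the radius range (alpha1 ~ alpha2
#'   makes gamma unidentifiable; flagged, not an error).
#' @slot design character description of the fixed-effect design.
#' @export
setClass("ShollFit",
  representation(summary = "data.frame", effects = "data.frame",
                 rhat = "numeric", converged = "logical",
                 gammaWide = "logical", design = "character"))

setMethod("show", "ShollFit", function(object) {
  cat("ShollFit (", object@design, ")\n", sep = "")
  cat(" converged:", object@converged,
      if (object@gammaWide) " [gamma weakly identified]" else "", "\n")
  print(object@summary, digits = 3)
})

#' Fit the hierarchical Bayesian Sholl change-point model
#'
#' Cell-level (tau, alpha1, alpha2, gamma) are drawn from animal-level
#' normals, animal-level from group-level linear predictors
#' (intercept + treatment + sex + interaction, as available in the data),
#' intersection counts are Poisson, and the change-point enters through a
#' continuous piecewise log-linear mean. Posterior sampling by JAGS with
#' fixed per-chain seeds; convergence is checked by split-Rhat < 1.05.
#' Curves with fewer than two nonzero rings are excluded with a warning.
#'
#' @param curves long data.frame(animal, cell, treatment, sex, radiusUm,
#'   intersections), e.g. from \code{\link{simulateShollCurves}} or built
#'   from \code{\link{shollIntersections}} output.
#' @param nChains,nAdapt,nBurn,nSample MCMC controls.
#' @param seed integer; chain c uses seed + c.
#' @return A \linkS4class{ShollFit}.
#' @export
fitShollModel <- function(curves, nChains = 2, nAdapt = 500, nBurn = 500,
                          nSample = 1000, seed = 1L) {
  keep <- stats::ave(curves$intersections, curves$cell,
                     FUN = function(v) sum(v > 0)) >= 2
  if (!all(keep)) {
    warning(sum(!keep & !duplicated(curves$cell)),
            " curve(s) with < 2 nonzero rings excluded")
    curves <- curves[keep, , drop = FALSE]
  }
  curves$cellF <- factor(curves$cell)
  curves$animalF <- factor(curves$animal)
  # reference level = first treatment/sex appearing in the data (by
  # convention the control group), not alphabetical order
  curves$treatment <- factor(curves$treatment,
                             levels = unique(curves$treatment))
  curves$sex <- factor(curves$sex, levels = unique(curves$sex))
  # rows must follow factor-level order: JAGS indexes cells/animals by level
  cellTab <- curves[match(levels(curves$cellF), as.character(curves$cell)), ]
  animTab <- curves[match(levels(curves$animalF),
                          as.character(curves$animal)), ]
  hasSex <- length(unique(animTab$sex)) > 1
  hasTrt <- length(unique(animTab$treatment)) > 1
  form <- if (hasTrt && hasSex) ~ treatment * sex else
    if (hasTrt) ~ treatment else if (hasSex) ~ sex else ~ 1
  X <- stats::model.matrix(form, animTab)
  rmin <- min(curves$radiusUm); rmax <- max(curves$radiusUm)

  dataList <- list(
    N = nrow(curves), y = curves$intersections, r = curves$radiusUm,
    cell = as.integer(curves$cellF),
    C = nlevels(curves$cellF),
    cellAnimal = as.integer(factor(cellTab$animal,
                                   levels = levels(curves$animalF))),
    A = nlevels(curves$animalF),
    X = X, P = ncol(X), rmin = rmin, rmax = rmax,
    gmid = (rmin + rmax) / 2)

  # initialize from per-curve ML fits for fast convergence
  cellInit <- t(vapply(levels(curves$cellF), function(cl) {
    cv <- curves[curves$cellF == cl, ]
    f <- tryCatch(fitShollCurve(data.frame(radiusUm = cv$radiusUm,
                                           intersections = cv$intersections)),
                  warning = function(w) NULL, error = function(e) NULL)
    if (is.null(f)) c(1, 0.05, -0.05, (rmin + rmax) / 2) else
      c(f$tau, max(min(f$alpha1, 0.45), -0.45),
        max(min(f$alpha2, 0.45), -0.45),
        max(min(f$gamma, rmax - 1), rmin + 1))
  }, numeric(4)))
  inits <- lapply(seq_len(nChains), function(ch) list(
    tau_c = cellInit[, 1], a1_c = cellInit[, 2], a2_c = cellInit[, 3],
    gam_c = cellInit[, 4],
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = as.integer(seed) + ch))

  model <- rjags::jags.model(textConnection(.shollJagsModel),
                             data = dataList, inits = inits,
                             n.chains = nChains, n.adapt = nAdapt,
                             quiet = TRUE)
  stats::update(model, nBurn, progress.bar = "none")
  mon <- c("beta_tau", "beta_a1", "beta_a2", "beta_gam")
  samp <- rjags::coda.samples(model, mon, n.iter = nSample,
                              progress.bar = "none")

  sm <- summary(samp)
  qs <- sm$quantiles
  mn <- sm$statistics
  coefNames <- colnames(X)
  prettyName <- function(v) {
    # with a single fixed-effect column JAGS drops the bracket index
    idx <- suppressWarnings(as.integer(sub(".*\\[(\\d+)\\]", "\\1", v)))
    idx[is.na(idx)] <- 1L
    par <- sub("beta_(\\w+).*", "\\1", v)
    par <- c(tau = "tau", a1 = "alpha1", a2 = "alpha2", gam = "gamma")[par]
    paste(par, coefNames[idx], sep = ":")
  }
  summaryDf <- data.frame(
    coefficient = prettyName(rownames(qs)),
    mean = mn[, "Mean"], lower = qs[, "2.5%"], upper = qs[, "97.5%"],
    row.names = NULL)
  gd <- coda::gelman.diag(samp, multivariate = FALSE, autoburnin = FALSE)
  rhat <- setNames(gd$psrf[, 1], prettyName(rownames(gd$psrf)))
  gRow <- summaryDf$coefficient == "gamma:(Intercept)"
  gammaCiWidth <- summaryDf$upper[gRow] - summaryDf$lower[gRow]
  effects <- summaryDf[grep("(treatment|sex)", summaryDf$coefficient), ,
                       drop = FALSE]
  new("ShollFit", summary = summaryDf, effects = effects, rhat = rhat,
      converged = all(is.finite(rhat)) && all(rhat < 1.05),
      gammaWide = isTRUE(gammaCiWidth > (rmax - rmin) / 3),
      design = paste(deparse(form), collapse = ""))
}
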