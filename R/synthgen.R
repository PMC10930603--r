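# Synthetic two-photon / confocal data generator with full ground truth.
# Emission intensities are fixed internal constants so that thresholding the
# noise-free image at the emission level reproduces the ground-truth mask.
.EMISSION <- c(microglia = 100, purkinje = 120)

#' SynthConfig: parameters of the synthetic image generator
#'
#' Holds the acquisition geometry and the biological parameters the
#' generator realizes. Defaults mirror the in-vivo acquisition protocol the
#' package targets: 101 um z-stacks at a 1 um step, imaged every 5 min for
#' an hour (12 timepoints).
#'
#' @slot imageShape named integer c(y, x, z), pixels per axis (each >= 16).
#' @slot voxelSizeUm named numeric c(y, x, z), micrometers per voxel.
#' @slot nTimepoints integer, timepoints in a time-lapse (default 12).
#' @slot dtMin numeric, minutes between timepoints (default 5).
#' @slot pclStartZ integer, first z-slice of the PCL (ML is above).
#' @slot microgliaDensity named numeric, cells per um^2 by layer
#'   (ML, PCL, GL, WM), interpreted in-plane.
#' @slot processTurnover named numeric in [0,1] by layer (ML, PCL): target
#'   motility index realized by tip extension/retraction per interval.
#' @slot bleedAlpha numeric in [0,1): fraction of the Purkinje-channel
#'   intensity added to the microglia channel.
#' @slot drift numeric scalar (max per-timepoint |translation| in px, drawn
#'   uniformly) or an explicit nTimepoints x 2 integer matrix of (dy, dx).
#' @slot noiseSd numeric, sd of additive Gaussian noise (clipped at 0).
#' @slot backgroundLevel numeric, constant background intensity.
#' @slot pclSomaSpacingUm numeric, mean Purkinje soma spacing along the PCL.
#' @slot somaPlacement "grid" (perturbed grid) or "poisson".
#' @slot groupEffects named list of named multiplier vectors, keyed by
#'   treatment ("ethanol") or treatment.sex ("ethanol.F"); multipliers apply
#'   to generator parameters, e.g. c(pclLinearDensity = 0.92).
#' @slot seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @export
setClass("SynthConfig",
  representation(imageShape = "integer", voxelSizeUm = "numeric",
    nTimepoints = "integer", dtMin = "numeric", pclStartZ = "integer",
    microgliaDensity = "numeric", processTurnover = "numeric",
    bleedAlpha = "numeric", drift = "ANY", noiseSd = "numeric",
    backgroundLevel = "numeric", pclSomaSpacingUm = "numeric",
    somaPlacement = "character", groupEffects = "list", seed = "integer"),
  validity = function(object) {
    s <- object@imageShape
    if (!all(c("y", "x", "z") %in% names(s))) return("imageShape needs y, x, z")
    if (any(s < 16L)) return("degenerate shape: every axis must be >= 16 px")
    if (any(object@microgliaDensity < 0)) return("densities must be >= 0")
    if (object@bleedAlpha < 0 || object@bleedAlpha >= 1)
      return("bleedAlpha must be in [0, 1)")
    if (any(object@processTurnover < 0 | object@processTurnover > 1))
      return("processTurnover must be in [0, 1]")
    if (object@pclStartZ < 2L || object@pclStartZ > s["z"])
      return("pclStartZ outside the z range")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@pclSomaSpacingUm <= 0) return("pclSomaSpacingUm must be > 0")
    if (!object@somaPlacement %in% c("grid", "poisson"))
      return("somaPlacement must be 'grid' or 'poisson'")
    TRUE
  })

#' Construct a SynthConfig
#'
#' @param imageShape named c(y, x, z) in pixels.
#' @param voxelSizeUm named c(y, x, z) in micrometers per voxel.
#' @param nTimepoints timepoints per time-lapse.
#' @param dtMin minutes between timepoints.
#' @param pclStartZ first PCL z-slice; default ~70\% of the stack depth.
#' @param microgliaDensity cells per um^2 by layer.
#' @param processTurnover target motility index per layer.
#' @param bleedAlpha channel bleed-through fraction.
#' @param drift max per-timepoint translation (px) or explicit offset matrix.
#' @param noiseSd additive Gaussian noise sd.
#' @param backgroundLevel constant background intensity.
#' @param pclSomaSpacingUm mean Purkinje soma spacing (um).
#' @param somaPlacement "grid" or "poisson".
#' @param groupEffects named list of multiplier vectors (see class doc).
#' @param seed integer RNG seed.
#' @return A \linkS4class{SynthConfig}.
#' @export
synthConfig <- function(imageShape = c(y = 96L, x = 96L, z = 101L),
                        voxelSizeUm = c(y = 1, x = 1, z = 1),
                        nTimepoints = 12L, dtMin = 5,
                        pclStartZ = NULL,
                        microgliaDensity = c(ML = 1.5e-4, PCL = 1.5e-4,
                                             GL = 2e-4, WM = 1.2e-4),
                        processTurnover = c(ML = 0.07, PCL = 0.10),
                        bleedAlpha = 0.15, drift = 0, noiseSd = 3,
                        backgroundLevel = 5, pclSomaSpacingUm = 30,
                        somaPlacement = "grid", groupEffects = list(),
                        seed = 1L) {
  imageShape <- as.integer(imageShape)
  names(imageShape) <- c("y", "x", "z")
  if (is.null(pclStartZ)) pclStartZ <- as.integer(round(0.7 * imageShape["z"]))
  if (length(processTurnover) == 1L && is.null(names(processTurnover)))
    processTurnover <- c(ML = unname(processTurnover),
                         PCL = unname(processTurnover))
  new("SynthConfig", imageShape = imageShape, voxelSizeUm = voxelSizeUm,
      nTimepoints = as.integer(nTimepoints), dtMin = dtMin,
      pclStartZ = as.integer(pclStartZ),
      microgliaDensity = microgliaDensity,
      processTurnover = processTurnover, bleedAlpha = bleedAlpha,
      drift = drift, noiseSd = noiseSd, backgroundLevel = backgroundLevel,
      pclSomaSpacingUm = pclSomaSpacingUm, somaPlacement = somaPlacement,
      groupEffects = groupEffects, seed = as.integer(seed))
}

#' Replace the seed of a SynthConfig
#' @param config a \linkS4class{SynthConfig}.
#' @param seed new integer seed.
#' @return The modified config.
#' @export
setConfigSeed <- function(config, seed) {
  config@seed <- as.integer(seed)
  config
}

setMethod("show", "SynthConfig", function(object) {
  s <- object@imageShape
  cat("SynthConfig:", s["y"], "x", s["x"], "x", s["z"], "px,",
      object@nTimepoints, "timepoints @", object@dtMin, "min\n")
  cat("  turnover:", paste(sprintf("%s=%g", names(object@processTurnover),
                                   object@processTurnover), collapse = " "),
      " bleed:", object@bleedAlpha, " noise sd:", object@noiseSd,
      " seed:", object@seed, "\n")
})

# multiplier resolution: product of all effect vectors whose key matches the
# treatment or treatment.sex of the group
.resolveEffects <- function(groupEffects, group) {
  mult <- numeric(0)
  if (is.null(group) || !length(groupEffects)) return(mult)
  keys <- character(0)
  if ("treatment" %in% names(group) && !is.na(group[["treatment"]])) {
    keys <- group[["treatment"]]
    if ("sex" %in% names(group) && !is.na(group[["sex"]]))
      keys <- c(keys, paste(group[["treatment"]], group[["sex"]], sep = "."))
  }
  for (k in keys) {
    eff <- groupEffects[[k]]
    if (is.null(eff)) next
    for (p in names(eff)) {
      cur <- if (p %in% names(mult)) mult[[p]] else 1
      mult[p] <- cur * eff[[p]]
    }
  }
  mult
}

.effectOn <- function(mult, param) if (param %in% names(mult)) mult[[param]] else 1

# rejection placement of cell centers with a minimum separation
.placeCenters <- function(n, ny, nx, minDist, margin) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n && tries < 4000) {
    tries <- tries + 1
    p <- c(runif(1, margin, ny - margin), runif(1, margin, nx - margin))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= minDist)
      pts <- rbind(pts, p)
  }
  pts
}

# grow one process as a persistent random walk on the pixel grid; marks occ
.growProcess <- function(yc, xc, angle, len, occ, maxR = 16) {
  ny <- nrow(occ); nx <- ncol(occ)
  pos <- c(yc + 4.5 * sin(angle), xc + 4.5 * cos(angle))
  dir <- angle
  path <- matrix(0L, 0, 2)
  last <- c(-1L, -1L)
  for (i in seq_len(len)) {
    px <- as.integer(round(pos))
    if (px[1] < 2 || px[1] > ny - 1 || px[2] < 2 || px[2] > nx - 1) break
    if (sqrt((px[1] - yc)^2 + (px[2] - xc)^2) > maxR) break
    if (!identical(px, last)) {
      if (occ[px[1], px[2]]) { if (nrow(path) > 0) break else { pos <- pos +
          c(sin(dir), cos(dir)); next } }
      occ[px[1], px[2]] <- TRUE
      path <- rbind(path, px)
      last <- px
    }
    dir <- dir + rnorm(1, 0, 0.35)
    pos <- pos + c(sin(dir), cos(dir))
  }
  list(path = path, occ = occ)
}

# build microglia cells for one layer; returns cells + 2-D occupancy
.buildLayerCells <- function(nCells, ny, nx, zRange, occ) {
  margin <- min(18, floor(min(ny, nx) / 2) - 1)
  centers <- .placeCenters(nCells, ny, nx,
                           minDist = min(34, min(ny, nx) - 2 * margin + 8),
                           margin = margin)
  cells <- list()
  for (i in seq_len(nrow(centers))) {
    yc <- round(centers[i, 1]); xc <- round(centers[i, 2])
    zc <- if (length(zRange) == 1) zRange else
      sample(seq(min(zRange), max(zRange)), 1)
    somaPx <- .discPixels(yc, xc, 3, ny, nx)
    occ[cbind(somaPx[, 1], somaPx[, 2])] <- TRUE
    # soma as a small sphere: full disc at zc, shrinking discs above/below
    somaVox <- cbind(somaPx, z = zc)
    for (dz in c(-2L, -1L, 1L, 2L)) {
      zz <- zc + dz
      if (zz < min(zRange) || zz > max(zRange)) next
      d <- .discPixels(yc, xc, 3 - abs(dz), ny, nx)
      somaVox <- rbind(somaVox, cbind(d, z = zz))
    }
    nProc <- 4L
    procs <- list()
    for (p in seq_len(nProc)) {
      ang <- 2 * pi * (p - 1) / nProc + runif(1, -0.3, 0.3)
      g <- .growProcess(yc, xc, ang, len = sample(10:18, 1), occ)
      occ <- g$occ
      if (nrow(g$path) >= 3) procs[[length(procs) + 1]] <- g$path
    }
    cells[[length(cells) + 1]] <- list(yc = yc, xc = xc, zc = zc,
                                       somaPx = somaPx, somaVox = somaVox,
                                       procs = procs)
  }
  list(cells = cells, occ = occ)
}

# one turnover transition for a layer: retract then extend k tip pixels so
# that (extended + retracted) / stable hits the target motility index
.turnoverStep <- function(cells, occ, turnover) {
  ny <- nrow(occ); nx <- ncol(occ)
  occPrev <- occ
  n <- sum(occ)
  # stochastic rounding keeps the mean motility index on target even when
  # the mask is small and k is strongly quantized
  kf <- turnover * n / (2 + turnover)
  k <- floor(kf) + (runif(1) < kf %% 1)
  if (k == 0) return(list(cells = cells, occ = occ))
  removed <- matrix(FALSE, ny, nx)
  # index of every process across cells
  procIdx <- do.call(rbind, lapply(seq_along(cells), function(ci)
    if (length(cells[[ci]]$procs))
      cbind(ci, seq_along(cells[[ci]]$procs)) else NULL))
  if (is.null(procIdx)) return(list(cells = cells, occ = occ))
  # retract
  nRet <- 0
  guard <- 0
  while (nRet < k && guard < 20 * k + 100) {
    guard <- guard + 1
    j <- sample(nrow(procIdx), 1)
    ci <- procIdx[j, 1]; pi <- procIdx[j, 2]
    path <- cells[[ci]]$procs[[pi]]
    if (nrow(path) <= 3) next
    tip <- path[nrow(path), ]
    cells[[ci]]$procs[[pi]] <- path[-nrow(path), , drop = FALSE]
    occ[tip[1], tip[2]] <- FALSE
    removed[tip[1], tip[2]] <- TRUE
    nRet <- nRet + 1
  }
  # extend: continue at tips, into pixels never part of the previous mask
  dirs <- cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  nExt <- 0
  guard <- 0
  while (nExt < nRet && guard < 40 * k + 200) {
    guard <- guard + 1
    j <- sample(nrow(procIdx), 1)
    ci <- procIdx[j, 1]; pi <- procIdx[j, 2]
    path <- cells[[ci]]$procs[[pi]]
    np <- nrow(path)
    if (np < 2) next
    tip <- path[np, ]
    heading <- atan2(path[np, 1] - path[np - 1, 1],
                     path[np, 2] - path[np - 1, 2])
    angs <- atan2(dirs[, 1], dirs[, 2])
    ord <- order(abs(((angs - heading + pi) %% (2 * pi)) - pi) +
                   runif(8, 0, 0.3))
    done <- FALSE
    for (d in ord) {
      cand <- tip + dirs[d, ]
      if (cand[1] < 2 || cand[1] > ny - 1 || cand[2] < 2 || cand[2] > nx - 1)
        next
      if (occ[cand[1], cand[2]] || occPrev[cand[1], cand[2]] ||
          removed[cand[1], cand[2]]) next
      if (sqrt((cand[1] - cells[[ci]]$yc)^2 +
               (cand[2] - cells[[ci]]$xc)^2) > 22) next
      cells[[ci]]$procs[[pi]] <- rbind(path, cand)
      occ[cand[1], cand[2]] <- TRUE
      nExt <- nExt + 1
      done <- TRUE
      break
    }
    if (!done) next
  }
  list(cells = cells, occ = occ)
}

# microglia voxel indices (linear, into a (ny, nx, nz) array) for one layer
.layerVoxels <- function(cells, ny, nx) {
  vox <- lapply(cells, function(cl) {
    pv <- if (length(cl$procs))
      cbind(do.call(rbind, cl$procs), z = cl$zc) else NULL
    rbind(cl$somaVox, pv)
  })
  v <- do.call(rbind, vox)
  as.integer(v[, 1] + (v[, 2] - 1) * ny + (v[, 3] - 1) * ny * nx)
}

# static Purkinje channel for the in-vivo geometry: quasi-planar dendrite
# arbors filling the ML, soma spheres in a monolayer at the ML/PCL boundary
.buildPurkinjeInvivo <- function(ny, nx, nz, pclStartZ, spacingPx) {
  vox <- matrix(integer(0), 0, 3)
  # dendritic arbors: wavy planes 3 px thick, spaced ~12 px in x
  xs0 <- seq(6, nx - 6, by = 12)
  mlZ <- seq_len(pclStartZ - 1)
  for (x0 in xs0) {
    phase <- runif(1, 0, 2 * pi)
    for (z in mlZ) {
      xz <- x0 + round(2 * sin(z / 6 + phase))
      cols <- intersect(xz + (-1):1, seq_len(nx))
      vox <- rbind(vox, cbind(rep(seq_len(ny), length(cols)),
                              rep(cols, each = ny), z))
    }
  }
  # soma monolayer: spheres of radius 8 at the boundary, jittered grid
  r <- 8
  zc <- min(nz - 2, pclStartZ + r - 2)
  gy <- seq(spacingPx / 2, ny - spacingPx / 4, by = spacingPx)
  gx <- seq(spacingPx / 2, nx - spacingPx / 4, by = spacingPx)
  centers <- expand.grid(y = gy, x = gx)
  centers$y <- pmin(ny - 4, pmax(4, centers$y + rnorm(nrow(centers), 0, 1.5)))
  centers$x <- pmin(nx - 4, pmax(4, centers$x + rnorm(nrow(centers), 0, 1.5)))
  somaCenters <- cbind(centers, z = zc)
  for (i in seq_len(nrow(centers))) {
    for (dz in -r:r) {
      zz <- zc + dz
      if (zz < 1 || zz > nz) next
      rr <- sqrt(max(0, r^2 - dz^2))
      if (rr < 0.5) next
      d <- .discPixels(centers$y[i], centers$x[i], rr, ny, nx)
      vox <- rbind(vox, cbind(d, z = zz))
    }
  }
  vox <- unique(vox)
  list(vox = as.integer(vox[, 1] + (vox[, 2] - 1) * ny +
                          (vox[, 3] - 1) * ny * nx),
       somaCenters = somaCenters)
}

#' Generate an in-vivo two-channel time-lapse with ground truth
#'
#' Builds branched microglia (soma spheres plus 1-px processes) whose tips
#' extend and retract so that the per-transition motility index of the
#' ground-truth masks equals the configured \code{processTurnover}; a static
#' Purkinje channel (quasi-planar ML arbors, a PCL soma monolayer);
#' channel bleed-through, per-timepoint drift, and additive noise (in that
#' order, noise last). Ground truth is recorded before noise and in
#' undrifted coordinates.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return A list with elements \code{stack} (\linkS4class{TimelapseStack})
#'   and \code{truth}: \code{mgProj} (per-layer list of per-timepoint 2-D
#'   masks), \code{mgVox} (per-timepoint microglia voxel indices),
#'   \code{pkVox} (static Purkinje voxel indices), \code{somaCenters},
#'   \code{pkSomaCenters}, \code{drift} (T x 2 integer offsets),
#'   \code{pclStartZ}, and \code{params} (realized parameter values).
#' @export
generateTimelapse <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  set.seed(config@seed)
  s <- config@imageShape
  ny <- s[["y"]]; nx <- s[["x"]]; nz <- s[["z"]]
  nT <- config@nTimepoints
  pclZ <- config@pclStartZ
  vy <- config@voxelSizeUm[["y"]]; vx <- config@voxelSizeUm[["x"]]
  areaUm2 <- ny * nx * vy * vx

  # microglia sit in a band around the layer boundary so that symmetric
  # layer substacks of >= 8 slices capture whole cells
  layers <- list(ML = c(max(4, pclZ - 8), max(5, pclZ - 4)),
                 PCL = c(min(nz - 3, pclZ + 3), min(nz - 3, pclZ + 7)))
  cellsByLayer <- list(); occByLayer <- list()
  for (ly in names(layers)) {
    dens <- config@microgliaDensity[[ly]]
    nCells <- max(1L, as.integer(round(dens * areaUm2)))
    built <- .buildLayerCells(nCells, ny, nx,
                              zRange = layers[[ly]], occ = matrix(FALSE, ny, nx))
    cellsByLayer[[ly]] <- built$cells
    occByLayer[[ly]] <- built$occ
  }

  mgProj <- list(ML = vector("list", nT), PCL = vector("list", nT))
  mgVox <- vector("list", nT)
  for (ly in names(layers)) mgProj[[ly]][[1]] <- occByLayer[[ly]]
  mgVox[[1]] <- c(.layerVoxels(cellsByLayer$ML, ny, nx),
                  .layerVoxels(cellsByLayer$PCL, ny, nx))
  for (t in 2:nT) {
    for (ly in names(layers)) {
      st <- .turnoverStep(cellsByLayer[[ly]], occByLayer[[ly]],
                          config@processTurnover[[ly]])
      cellsByLayer[[ly]] <- st$cells
      occByLayer[[ly]] <- st$occ
      mgProj[[ly]][[t]] <- st$occ
    }
    mgVox[[t]] <- c(.layerVoxels(cellsByLayer$ML, ny, nx),
                    .layerVoxels(cellsByLayer$PCL, ny, nx))
  }

  pk <- .buildPurkinjeInvivo(ny, nx, nz, pclZ,
                             spacingPx = config@pclSomaSpacingUm / vx)

  # drift offsets relative to timepoint 1
  if (is.matrix(config@drift)) {
    drift <- config@drift
  } else {
    amp <- as.integer(round(config@drift))
    drift <- cbind(dy = c(0L, sample(-amp:amp, nT - 1, replace = TRUE)),
                   dx = c(0L, sample(-amp:amp, nT - 1, replace = TRUE)))
  }

  # heterogeneous Purkinje brightness (static over time): needed so that the
  # bleed-through slope is identifiable from Purkinje-only pixels
  pkIntensity <- .EMISSION["purkinje"] * runif(length(pk$vox), 0.75, 1.25)

  data <- array(0, dim = c(nT, nz, 2L, ny, nx))
  for (t in seq_len(nT)) {
    v1 <- array(0, dim = c(ny, nx, nz)); v1[mgVox[[t]]] <- .EMISSION["microglia"]
    v2 <- array(0, dim = c(ny, nx, nz)); v2[pk$vox] <- pkIntensity
    v1 <- v1 + config@bleedAlpha * v2
    for (z in seq_len(nz)) {
      f1 <- v1[, , z]; f2 <- v2[, , z]
      if (any(drift[t, ] != 0)) {
        f1 <- .shift2d(f1, drift[t, 1], drift[t, 2])
        f2 <- .shift2d(f2, drift[t, 1], drift[t, 2])
      }
      f1 <- f1 + config@backgroundLevel
      f2 <- f2 + config@backgroundLevel
      if (config@noiseSd > 0) {
        f1 <- f1 + rnorm(length(f1), 0, config@noiseSd)
        f2 <- f2 + rnorm(length(f2), 0, config@noiseSd)
      }
      data[t, z, 1, , ] <- pmax(0, f1)
      data[t, z, 2, , ] <- pmax(0, f2)
    }
  }

  somaCenters <- do.call(rbind, lapply(names(layers), function(ly)
    do.call(rbind, lapply(cellsByLayer[[ly]], function(cl)
      data.frame(layer = ly, y = cl$yc, x = cl$xc, z = cl$zc)))))

  stack <- TimelapseStack(data, voxelSizeUm = config@voxelSizeUm,
                          dtMin = config@dtMin)
  truth <- list(mgProj = mgProj, mgVox = mgVox, pkVox = pk$vox,
                somaCenters = somaCenters, pkSomaCenters = pk$somaCenters,
                drift = drift, pclStartZ = pclZ,
                params = list(processTurnover = config@processTurnover,
                              bleedAlpha = config@bleedAlpha,
                              noiseSd = config@noiseSd,
                              backgroundLevel = config@backgroundLevel,
                              emission = .EMISSION,
                              emissionThreshold = c(
                                microglia = unname(.EMISSION["microglia"]),
                                purkinje = 0.75 * unname(.EMISSION["purkinje"]))))
  list(stack = stack, truth = truth)
}

# sample soma positions inside a polygon at a target density (cells/um^2)
.placeSomasInPolygon <- function(poly, density, placement, pxUm) {
  areaUm2 <- polygonArea(poly) * pxUm^2
  if (placement == "poisson") {
    n <- rpois(1, density * areaUm2)
    bb <- apply(poly, 2, range)
    pts <- matrix(numeric(0), 0, 2)
    while (nrow(pts) < n) {
      cand <- cbind(runif(2 * n + 20, bb[1, 1], bb[2, 1]),
                    runif(2 * n + 20, bb[1, 2], bb[2, 2]))
      cand <- cand[pointsInPolygon(cand, poly), , drop = FALSE]
      pts <- rbind(pts, cand)
    }
    pts[seq_len(n), , drop = FALSE]
  } else {
    spacing <- 1 / sqrt(density) / pxUm   # px between grid points
    bb <- apply(poly, 2, range)
    gseq <- function(lo, hi) {
      s <- lo + runif(1, 0, spacing)
      if (s > hi) numeric(0) else seq(s, hi, by = spacing)
    }
    gx <- gseq(bb[1, 1], bb[2, 1])
    gy <- gseq(bb[1, 2], bb[2, 2])
    if (!length(gx) || !length(gy)) return(matrix(numeric(0), 0, 2))
    g <- as.matrix(expand.grid(x = gx, y = gy))
    g <- g + matrix(rnorm(length(g), 0, 0.08 * spacing), ncol = 2)
    g[pointsInPolygon(g, poly), , drop = FALSE]
  }
}

#' Generate a fixed-tissue section with layer ROIs and ground truth
#'
#' Builds a single-timepoint two-channel z-stack of a layered lobule: three
#' stacked layer ROIs (ML+PCL combined, GL, WM) separated by wavy
#' boundaries, a curved PCL polyline carrying Purkinje soma spheres at the
#' configured spacing, Purkinje dendrites rising through the ML, and
#' microglia somas (with short processes) placed per layer by a perturbed
#' grid or a Poisson point process. Group effects multiply densities and
#' the PCL linear density before placement.
#'
#' @param config a \linkS4class{SynthConfig}; \code{imageShape} sets the
#'   section size.
#' @param group optional named character c(treatment=, sex=) used to resolve
#'   \code{groupEffects}.
#' @return A list: \code{image} (\linkS4class{TimelapseStack} with one
#'   timepoint), \code{rois} (list of \linkS4class{LayerROI}: ML_PCL, GL,
#'   WM), and \code{truth} with \code{mgSomas} (data.frame layer/y/x/z),
#'   \code{pkSomas}, \code{pclPath} (polyline, (x, y) px), \code{mgVox},
#'   \code{pkVox}, and \code{params} (realized values incl.
#'   \code{pclLinearDensityUm}).
#' @export
generateFixedSection <- function(config, group = NULL) {
  stopifnot(is(config, "SynthConfig"))
  set.seed(config@seed)
  s <- config@imageShape
  ny <- s[["y"]]; nx <- s[["x"]]; nz <- s[["z"]]
  pxUm <- config@voxelSizeUm[["x"]]
  mult <- .resolveEffects(config@groupEffects, group)

  # wavy layer boundaries (y grows downward: ML+PCL on top, then GL, WM)
  xs <- seq(1, nx, by = 8)
  if (xs[length(xs)] != nx) xs <- c(xs, nx)
  amp <- 0.05 * ny; lam <- nx / 1.5; phase <- runif(1, 0, 2 * pi)
  b1 <- 0.38 * ny + amp * sin(2 * pi * xs / lam + phase)
  b2 <- 0.72 * ny + amp * sin(2 * pi * xs / lam + phase)
  polyML <- cbind(x = c(xs, rev(xs)), y = c(rep(1, length(xs)), rev(b1)))
  polyGL <- cbind(x = c(xs, rev(xs)), y = c(b1, rev(b2)))
  polyWM <- cbind(x = c(xs, rev(xs)), y = c(b2, rep(ny, length(xs))))
  rois <- list(ML_PCL = LayerROI("ML_PCL", polyML, pxUm),
               GL = LayerROI("GL", polyGL, pxUm),
               WM = LayerROI("WM", polyWM, pxUm))

  # PCL path: just above the ML_PCL/GL boundary
  pclPath <- cbind(x = xs, y = b1 - 12)
  segLen <- sqrt(rowSums(diff(pclPath)^2))
  cumLen <- c(0, cumsum(segLen))
  pathLenUm <- sum(segLen) * pxUm

  # Purkinje somas along the path; linear-density effect rescales spacing
  fLin <- .effectOn(mult, "pclLinearDensity")
  spacingUm <- config@pclSomaSpacingUm / fLin
  spacingPx <- spacingUm / pxUm
  arc <- runif(1, 0, spacingPx)
  pos <- c()
  while (arc < cumLen[length(cumLen)]) {
    pos <- c(pos, arc)
    arc <- arc + spacingPx * exp(rnorm(1, 0, 0.04))
  }
  interpPath <- function(a) {
    i <- findInterval(a, cumLen, rightmost.closed = TRUE)
    i <- pmin(i, length(segLen))
    w <- (a - cumLen[i]) / segLen[i]
    cbind(x = pclPath[i, 1] + w * (pclPath[i + 1, 1] - pclPath[i, 1]),
          y = pclPath[i, 2] + w * (pclPath[i + 1, 2] - pclPath[i, 2]))
  }
  pkCenters <- if (length(pos)) interpPath(pos) else matrix(numeric(0), 0, 2)

  rSoma <- 8 / pxUm
  zc <- round(nz / 2)
  pkList <- list()
  for (i in seq_len(nrow(pkCenters))) {
    for (dz in -floor(rSoma):floor(rSoma)) {
      zz <- zc + dz
      if (zz < 1 || zz > nz) next
      rr <- sqrt(max(0, rSoma^2 - dz^2))
      if (rr < 0.5) next
      d <- .discPixels(pkCenters[i, 2], pkCenters[i, 1], rr, ny, nx)
      pkList[[length(pkList) + 1]] <- cbind(d, z = zz)
    }
  }
  # dendrite trunks rising from each soma through the ML (2 px wide, forked)
  for (i in seq_len(nrow(pkCenters))) {
    x0 <- round(pkCenters[i, 1]); y0 <- round(pkCenters[i, 2] - rSoma)
    if (y0 < 4) next
    forkY <- max(3, round(y0 * runif(1, 0.35, 0.6)))
    main <- .linePixels(y0, x0, forkY, x0 + sample(-3:3, 1))
    tipL <- .linePixels(forkY, main[nrow(main), 2],
                        max(2, round(forkY * 0.2)),
                        max(2, min(nx - 1, main[nrow(main), 2] - sample(3:8, 1))))
    tipR <- .linePixels(forkY, main[nrow(main), 2],
                        max(2, round(forkY * 0.2)),
                        max(2, min(nx - 1, main[nrow(main), 2] + sample(3:8, 1))))
    tr <- rbind(main, tipL, tipR)
    tr <- tr[tr[, 1] >= 1 & tr[, 1] <= ny & tr[, 2] >= 1 & tr[, 2] <= nx - 1, ,
             drop = FALSE]
    zs <- intersect(zc + (-4:4), seq_len(nz))
    for (zz in zs)
      pkList[[length(pkList) + 1]] <-
        rbind(cbind(y = tr[, 1], x = tr[, 2], z = zz),
              cbind(y = tr[, 1], x = tr[, 2] + 1L, z = zz))
  }

  # sparse Purkinje axon tracts in the WM
  wmTop <- max(b2); nAxons <- max(1, round(nx / 48))
  for (i in seq_len(nAxons)) {
    y0 <- round(runif(1, min(wmTop + 4, ny - 2), ny - 2))
    ln <- .linePixels(y0, 2L, max(2, y0 + sample(-6:6, 1)), nx - 1L)
    zs <- intersect(zc + (-3:3), seq_len(nz))
    for (zz in zs)
      pkList[[length(pkList) + 1]] <- cbind(y = ln[, 1], x = ln[, 2], z = zz)
  }
  pkVox <- do.call(rbind, pkList)
  pkVox <- pkVox[!duplicated(pkVox[, 1] + (pkVox[, 2] - 1) * ny +
                               (pkVox[, 3] - 1) * ny * nx), , drop = FALSE]

  # microglia somas + short processes, per layer
  mgSomas <- NULL
  mgList <- list()
  densities <- c(ML_PCL = unname(config@microgliaDensity["ML"]),
                 GL = unname(config@microgliaDensity["GL"]),
                 WM = unname(config@microgliaDensity["WM"]))
  for (ly in names(rois)) {
    dens <- densities[[ly]] * .effectOn(mult, paste0("microgliaDensity.", ly))
    pts <- .placeSomasInPolygon(rois[[ly]]@polygon, dens,
                                config@somaPlacement, pxUm)
    if (nrow(pts) == 0) next
    zs <- sample(5:max(6, nz - 5), nrow(pts), replace = TRUE)
    # cells too close to the field edge are not drawn and not part of truth
    drawable <- pts[, 2] >= 6 & pts[, 2] <= ny - 6 &
      pts[, 1] >= 6 & pts[, 1] <= nx - 6
    if (!any(drawable)) next
    pts <- pts[drawable, , drop = FALSE]; zs <- zs[drawable]
    mgSomas <- rbind(mgSomas, data.frame(layer = ly, y = pts[, 2],
                                         x = pts[, 1], z = zs))
    occ <- matrix(FALSE, ny, nx)
    for (i in seq_len(nrow(pts))) {
      yc <- round(pts[i, 2]); xc <- round(pts[i, 1]); zci <- zs[i]
      for (dz in -2:2) {
        zz <- zci + dz
        if (zz < 1 || zz > nz) next
        d <- .discPixels(yc, xc, 3.5 - abs(dz), ny, nx)
        mgList[[length(mgList) + 1]] <- cbind(d, z = zz)
      }
      nP <- sample(3:5, 1)
      for (p in seq_len(nP)) {
        g <- .growProcess(yc, xc, 2 * pi * p / nP + runif(1, -0.4, 0.4),
                          len = sample(6:10, 1), occ, maxR = 12)
        occ <- g$occ
        if (nrow(g$path))
          mgList[[length(mgList) + 1]] <- cbind(g$path, z = zci)
      }
    }
  }
  mgVox <- do.call(rbind, mgList)
  if (is.null(mgVox)) mgVox <- matrix(integer(0), 0, 3)
  if (nrow(mgVox))
    mgVox <- mgVox[!duplicated(mgVox[, 1] + (mgVox[, 2] - 1) * ny +
                                 (mgVox[, 3] - 1) * ny * nx), , drop = FALSE]

  toIdx <- function(v) as.integer(v[, 1] + (v[, 2] - 1) * ny +
                                    (v[, 3] - 1) * ny * nx)
  data <- array(0, dim = c(1L, nz, 2L, ny, nx))
  v1 <- array(0, dim = c(ny, nx, nz))
  v2 <- array(0, dim = c(ny, nx, nz))
  if (nrow(mgVox)) v1[toIdx(mgVox)] <- .EMISSION["microglia"]
  if (nrow(pkVox)) v2[toIdx(pkVox)] <-
    .EMISSION["purkinje"] * runif(nrow(pkVox), 0.75, 1.25)
  v1 <- v1 + config@bleedAlpha * v2 + config@backgroundLevel
  v2 <- v2 + config@backgroundLevel
  if (config@noiseSd > 0) {
    v1 <- v1 + array(rnorm(length(v1), 0, config@noiseSd), dim = dim(v1))
    v2 <- v2 + array(rnorm(length(v2), 0, config@noiseSd), dim = dim(v2))
  }
  for (z in seq_len(nz)) {
    data[1, z, 1, , ] <- pmax(0, v1[, , z])
    data[1, z, 2, , ] <- pmax(0, v2[, , z])
  }

  image <- TimelapseStack(data, voxelSizeUm = config@voxelSizeUm,
                          dtMin = config@dtMin)
  truth <- list(
    mgSomas = mgSomas,
    pkSomas = if (nrow(pkCenters)) data.frame(x = pkCenters[, 1],
                                              y = pkCenters[, 2], z = zc)
              else data.frame(x = numeric(0), y = numeric(0), z = numeric(0)),
    pclPath = pclPath, mgVox = mgVox, pkVox = pkVox,
    params = list(spacingUm = spacingUm,
                  pclLinearDensityUm = 1 / spacingUm,
                  effects = mult,
                  pathLengthUm = pathLenUm,
                  densities = densities))
  list(image = image, rois = rois, truth = truth)
}

#' Generate a laser-ablation injury time series with ground truth
#'
#' A fixed autofluorescent core disk with microglia processes converging on
#' it: the microglia front is an annulus whose inner radius shrinks linearly
#' at \code{ratePx} pixels per interval (never below the core radius), with
#' radial process spokes outside. The true front polygons and the analytic
#' normalized proximity series are returned.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param coreRadiusPx radius of the injury core (px).
#' @param frontRadiusPx initial front radius (px).
#' @param ratePx radial front advance per interval (px); 0 freezes the front.
#' @return A list: \code{stack}, \code{truth} with \code{corePolygon},
#'   \code{frontPolygons}, \code{frontRadii}, and \code{proximity}.
#' @export
generateInjurySeries <- function(config, coreRadiusPx = 10,
                                 frontRadiusPx = 30, ratePx = 2) {
  stopifnot(is(config, "SynthConfig"))
  set.seed(config@seed)
  s <- config@imageShape
  ny <- s[["y"]]; nx <- s[["x"]]; nz <- min(s[["z"]], 8L)
  nT <- config@nTimepoints
  cy <- ny / 2; cx <- nx / 2
  if (cy - frontRadiusPx < 2 || cx - frontRadiusPx < 2)
    stop("core/front must lie inside the field")

  ang <- seq(0, 2 * pi, length.out = 73)[-73]
  circlePoly <- function(r) cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
  radii <- pmax(coreRadiusPx, frontRadiusPx - ratePx * (seq_len(nT) - 1))

  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  dd <- sqrt((yy - cy)^2 + (xx - cx)^2)
  core2d <- dd <= coreRadiusPx
  spokes <- (floor((atan2(yy - cy, xx - cx) + pi) / (2 * pi) * 24) %% 2) == 0

  data <- array(0, dim = c(nT, nz, 2L, ny, nx))
  for (t in seq_len(nT)) {
    rF <- radii[t]
    mg2d <- (dd >= rF & dd <= rF + 6) | (dd > rF + 6 & spokes)
    frame <- matrix(0, ny, nx)
    frame[mg2d] <- .EMISSION["microglia"]
    frame[core2d] <- .EMISSION["microglia"] * 1.5  # autofluorescent debris
    for (z in seq_len(nz)) {
      f <- frame + config@backgroundLevel
      if (config@noiseSd > 0) f <- f + rnorm(length(f), 0, config@noiseSd)
      data[t, z, 1, , ] <- pmax(0, f)
      data[t, z, 2, , ] <- pmax(0, config@backgroundLevel +
        if (config@noiseSd > 0) rnorm(ny * nx, 0, config@noiseSd) else 0)
    }
  }
  aCore <- polygonArea(circlePoly(coreRadiusPx))
  aFront <- vapply(radii, function(r) polygonArea(circlePoly(r)), numeric(1))
  truth <- list(corePolygon = circlePoly(coreRadiusPx),
                frontPolygons = lapply(radii, circlePoly),
                frontRadii = radii,
                proximity = (aFront - aCore) / (aFront[1] - aCore))
  list(stack = TimelapseStack(data, voxelSizeUm = config@voxelSizeUm,
                              dtMin = config@dtMin),
       truth = truth)
}

#' Generate a 3-D region with an exact target occupancy
#'
#' Fills a (y, x, z) region with cell-like structures (short 3-D line
#' segments for sparse microglia-like content; stacked slabs for dense
#' Purkinje-like content) until the foreground voxel count equals
#' \code{round(occupancy * prod(dims))} exactly, then emits an image at the
#' class emission intensity plus background and noise. Used to reproduce
#' volume-fraction regimes with known truth.
#'
#' @param dims named c(y, x, z) region size in voxels.
#' @param occupancy target foreground fraction in [0, 1].
#' @param label "microglia" or "purkinje" (sets the emission intensity and
#'   structure style: segments when occupancy <= 0.05, slabs otherwise).
#' @param noiseSd additive Gaussian noise sd.
#' @param backgroundLevel constant background.
#' @param seed RNG seed.
#' @return list(image = numeric array (y, x, z), mask = logical array,
#'   occupancy = realized fraction).
#' @export
generateOccupancyRegion <- function(dims, occupancy, label = "microglia",
                                    noiseSd = 2, backgroundLevel = 5,
                                    seed = 1L) {
  stopifnot(occupancy >= 0, occupancy <= 1)
  set.seed(seed)
  ny <- dims[["y"]]; nx <- dims[["x"]]; nz <- dims[["z"]]
  nvox <- as.numeric(ny) * nx * nz
  target <- round(occupancy * nvox)
  mask <- array(FALSE, dim = c(ny, nx, nz))
  total <- 0
  if (target > 0 && occupancy > 0.05) {
    # dense content: fill wavy slabs until just short of target
    xs0 <- seq(2, nx - 1, by = max(2, round(1 / occupancy)))
    for (x0 in xs0) {
      idx <- cbind(rep(seq_len(ny), nz), x0, rep(seq_len(nz), each = ny))
      new <- idx[!mask[idx], , drop = FALSE]
      if (total + nrow(new) > target) {
        new <- new[sample(nrow(new), target - total), , drop = FALSE]
      }
      mask[new] <- TRUE
      total <- total + nrow(new)
      if (total >= target) break
    }
  }
  guard <- 0
  while (total < target && guard < 1e6) {
    guard <- guard + 1
    y0 <- sample(2:(ny - 1), 1); x0 <- sample(2:(nx - 1), 1)
    z0 <- sample(seq_len(nz), 1)
    len <- sample(12:30, 1)
    th <- runif(1, 0, 2 * pi)
    y1 <- max(1, min(ny, y0 + round(len * sin(th))))
    x1 <- max(1, min(nx, x0 + round(len * cos(th))))
    seg <- .linePixels(y0, x0, y1, x1)
    idx <- cbind(seg, z = z0)
    new <- idx[!mask[idx], , drop = FALSE]
    if (total + nrow(new) > target)
      new <- new[seq_len(target - total), , drop = FALSE]
    if (nrow(new)) {
      mask[new] <- TRUE
      total <- total + nrow(new)
    }
  }
  emission <- .EMISSION[[label]]
  img <- array(backgroundLevel, dim = dim(mask))
  img[mask] <- img[mask] + emission
  if (noiseSd > 0)
    img <- img + array(rnorm(length(img), 0, noiseSd), dim = dim(img))
  list(image = pmax(img, 0), mask = mask, occupancy = total / nvox)
}
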