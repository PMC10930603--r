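# End-to-end orchestration: in-vivo and fixed-tissue runs on synthetic (or
# imported) data, a long-format metric table, and group summaries.

.truthVolume <- function(idx, dims) {
  v <- array(FALSE, dim = dims)  # (y, x, z)
  v[idx] <- TRUE
  v
}

# (y, x, z) logical -> (z, y, x) to match getFrame layout
.toZYX <- function(v) aperm(v, c(3, 1, 2))

.metricRow <- function(animal, sex, treatment, section, timepoint, layer,
                       metric, value, units) {
  data.frame(animal = animal, sex = sex, treatment = treatment,
             section = section, timepoint = timepoint, layer = layer,
             metric = metric, value = value, units = units,
             stringsAsFactors = FALSE)
}

#' Run the in-vivo analysis pipeline on one synthetic animal
#'
#' Generates a time-lapse from the config, then applies the full chain:
#' drift correction, bleed-through estimation (on ground-truth
#' Purkinje-only voxels) and subtraction, optional temporal PCA denoising,
#' ML/PCL layer substacks, per-timepoint binarization, and computes the
#' motility index, surveillance ratio, volume fractions, normalized
#' microglia-Purkinje interaction, dynamic interaction index, and coverage
#' index for both layers.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param animal,sex,treatment metadata carried into the table.
#' @param nSlices slices per layer substack (default: largest symmetric
#'   choice around the configured PCL boundary).
#' @param threshold binarization threshold (default half the microglia
#'   emission intensity).
#' @param minSize component size exclusion for binarization.
#' @param denoiseK optional PCA component count; NULL skips denoising.
#' @return list(table = long metric data.frame, truth = generator truth,
#'   drift = estimated drift, alpha = estimated bleed fraction).
#' @export
runInvivo <- function(config, animal = "a1", sex = "F", treatment = "saline",
                      nSlices = NULL, threshold = 50, minSize = 5,
                      denoiseK = NULL) {
  gen <- generateTimelapse(config)
  stack <- gen$stack; truth <- gen$truth
  s <- config@imageShape
  dims <- c(s[["y"]], s[["x"]], s[["z"]])

  dc <- correctDrift(stack)
  pkOnly <- .truthVolume(truth$pkVox, dims)
  pkOnly[truth$mgVox[[1]]] <- FALSE
  alpha <- estimateBleedthrough(dc$stack, .toZYX(pkOnly), t = 1)$alpha
  clean <- subtractBleedthrough(dc$stack, alpha)
  if (!is.null(denoiseK)) clean <- pcaDenoise(clean, denoiseK)

  pclZ <- truth$pclStartZ
  nz <- dims[3]
  if (is.null(nSlices)) nSlices <- min(pclZ - 1, nz - pclZ + 1)
  layers <- splitLayers(clean, pclZ, nSlices)

  nT <- nTimepoints(stack)
  tab <- NULL
  for (ly in names(layers)) {
    sub <- layers[[ly]]
    mgMasks <- list(); mgCounts <- numeric(nT)
    ovCounts <- numeric(nT); pkCounts <- numeric(nT)
    ivMasks <- list()
    for (t in seq_len(nT)) {
      mg3 <- binarizeObjects(getFrame(sub, t, "microglia"), threshold,
                             minSize = minSize)
      pk3 <- binarizeObjects(getFrame(sub, t, "purkinje"), threshold,
                             minSize = minSize)
      ov <- interactionOverlap(mg3, pk3)
      # frames (and hence these masks) are laid out (z, y, x)
      mgMasks[[t]] <- maxProject(maskArray(mg3), zAxis = 1)
      ivMasks[[t]] <- maxProject(maskArray(ov$mask), zAxis = 1)
      mgCounts[t] <- maskSize(mg3)
      pkCounts[t] <- maskSize(pk3)
      ovCounts[t] <- ov$count
    }
    mi <- motilityIndex(mgMasks)
    sr <- surveillanceRatio(mgMasks)
    ni <- normalizedInteraction(ovCounts, mgCounts)
    dii <- dynamicInteractionIndex(ivMasks)
    cov <- coverageIndex(ivMasks)
    vol <- length(maskArray(binarizeObjects(getFrame(sub, 1, 1), threshold)))
    add <- function(metric, value, units)
      .metricRow(animal, sex, treatment, NA, NA, ly, metric, value, units)
    tab <- rbind(tab,
      add("motility_index", mi$mean, "ratio"),
      add("surveillance_ratio", sr, "ratio"),
      add("volume_fraction_microglia", mean(mgCounts) / vol, "fraction"),
      add("volume_fraction_purkinje", mean(pkCounts) / vol, "fraction"),
      add("normalized_interaction", ni$mean, "fraction"),
      add("dynamic_interaction_index", dii$mean, "ratio"),
      add("coverage_index", cov, "fraction"))
  }
  list(table = tab, truth = truth, drift = dc$drift, alpha = alpha)
}

# rasterize a polygon to a logical (y, x) matrix
.polygonMask <- function(poly, ny, nx) {
  g <- cbind(rep(seq_len(nx), each = ny), rep(seq_len(ny), nx))  # (x, y)
  inside <- pointsInPolygon(g, poly)
  matrix(inside, ny, nx)
}

#' Run the fixed-tissue analysis pipeline on synthetic sections
#'
#' For every animal in the design and every section, generates a fixed
#' section (group effects resolved from the config), detects microglia and
#' Purkinje somas, and computes per-layer density, the whole-lobule spacing
#' index, Purkinje cell linear frequency, per-layer volume fractions, and
#' the normalized microglia-Purkinje interaction (ML+PCL and WM; the GL is
#' excluded from interaction analysis). Per-section values are averaged
#' into one animal-level row per metric.
#'
#' @param config a \linkS4class{SynthConfig}; its seed anchors the
#'   per-animal, per-section seeds.
#' @param design data.frame(animal, sex, treatment), one row per animal.
#' @param nSections sections per animal (default 3).
#' @param threshold binarization threshold.
#' @param interactions logical; compute 3-D volume fractions and overlaps
#'   (the slowest step).
#' @return list(table = long metric data.frame with per-section and
#'   animal-mean (section = NA) rows, truths = list of generator truths).
#' @export
runFixed <- function(config, design = data.frame(animal = "a1", sex = "F",
                                                 treatment = "saline"),
                     nSections = 3, threshold = 50, interactions = FALSE) {
  tab <- NULL; truths <- list()
  s <- config@imageShape
  ny <- s[["y"]]; nx <- s[["x"]]; nz <- s[["z"]]
  pxUm <- config@voxelSizeUm[["x"]]
  for (i in seq_len(nrow(design))) {
    animal <- design$animal[i]; sex <- design$sex[i]
    treatment <- design$treatment[i]
    secTabs <- NULL
    for (sec in seq_len(nSections)) {
      cfg <- setConfigSeed(config, config@seed + 131L * i + sec)
      gen <- generateFixedSection(cfg, group = c(treatment = treatment,
                                                 sex = sex))
      truths[[paste(animal, sec, sep = "_")]] <- gen$truth
      mgProj <- maxProject(getFrame(gen$image, 1, "microglia"))
      pkProj <- maxProject(getFrame(gen$image, 1, "purkinje"))
      mgMask <- binarizeObjects(mgProj, threshold, minSize = 5,
                                pixelSizeUm = pxUm, label = "microglia")
      mgSomas <- detectSomas(mgMask, somaMinSize = 12, somaMaxSize = 200,
                             openRadius = 2)
      pkMask <- binarizeObjects(pkProj, threshold, minSize = 20,
                                pixelSizeUm = pxUm, label = "purkinje")
      pkSomas <- detectSomas(pkMask, somaMinSize = 60, somaMaxSize = 600,
                             openRadius = 5)
      rows <- NULL
      wholeCount <- 0; wholeArea <- 0
      for (ly in names(gen$rois)) {
        dd <- somaDensity(mgSomas, gen$rois[[ly]])
        wholeCount <- wholeCount + dd$count; wholeArea <- wholeArea + dd$areaUm2
        rows <- rbind(rows, .metricRow(animal, sex, treatment, sec, NA, ly,
                                       "microglia_density", dd$density,
                                       "per_um2"))
      }
      rows <- rbind(rows, .metricRow(animal, sex, treatment, sec, NA,
                                     "lobule", "microglia_density",
                                     wholeCount / wholeArea, "per_um2"))
      if (nrow(mgSomas) >= 2) {
        si <- spacingIndex(mgSomas, areaUm2 = wholeArea, pixelSizeUm = pxUm)
        rows <- rbind(rows, .metricRow(animal, sex, treatment, sec, NA,
                                       "lobule", "spacing_index",
                                       si$spacingIndex, "ratio"))
      }
      lf <- linearFrequency(pkSomas, gen$truth$pclPath, pixelSizeUm = pxUm)
      rows <- rbind(rows, .metricRow(animal, sex, treatment, sec, NA, "PCL",
                                     "linear_frequency", lf$linearFrequency,
                                     "per_um"))
      if (interactions) {
        mg3 <- binarizeObjects(aperm(getFrame(gen$image, 1, "microglia"),
                                     c(2, 3, 1)), threshold)
        pk3 <- binarizeObjects(aperm(getFrame(gen$image, 1, "purkinje"),
                                     c(2, 3, 1)), threshold)
        for (ly in c("ML_PCL", "WM")) {
          reg2d <- .polygonMask(gen$rois[[ly]]@polygon, ny, nx)
          reg <- array(reg2d, dim = c(ny, nx, nz))
          vfm <- volumeFraction(mg3, reg)
          vfp <- volumeFraction(pk3, reg)
          ovC <- sum(maskArray(mg3) & maskArray(pk3) & reg)
          mgC <- sum(maskArray(mg3) & reg)
          ni <- normalizedInteraction(ovC, mgC)
          rows <- rbind(rows,
            .metricRow(animal, sex, treatment, sec, NA, ly,
                       "volume_fraction_microglia", vfm, "fraction"),
            .metricRow(animal, sex, treatment, sec, NA, ly,
                       "volume_fraction_purkinje", vfp, "fraction"),
            .metricRow(animal, sex, treatment, sec, NA, ly,
                       "normalized_interaction", ni$mean, "fraction"))
        }
      }
      secTabs <- rbind(secTabs, rows)
    }
    # animal-level value = equal-weight mean of the sections
    agg <- stats::aggregate(value ~ layer + metric + units, secTabs, mean)
    tab <- rbind(tab, secTabs,
                 .metricRow(animal, sex, treatment, NA, NA, agg$layer,
                            agg$metric, agg$value, agg$units))
  }
  list(table = tab, truths = truths)
}

#' Group means, SEM, and percent differences of a metric
#'
#' Aggregates a metric table to per-animal values (mean over sections /
#' layers present after filtering), then reports per-group mean, SEM (NA
#' for n = 1), and the percent difference of each group relative to the
#' reference group: 100 * (1 - mean_group / mean_reference).
#'
#' @param table long metric data.frame (see \code{\link{runFixed}}).
#' @param metric metric name to summarize.
#' @param by grouping columns, e.g. "treatment" or c("treatment", "sex").
#' @param layer optional layer filter.
#' @param reference reference group level of \code{by[1]} (default:
#'   "saline" when present, else the first level).
#' @return data.frame with group columns, n, mean, sem, percentDifference.
#' @export
groupSummary <- function(table, metric, by = "treatment", layer = NULL,
                         reference = NULL) {
  d <- table[table$metric == metric, , drop = FALSE]
  if (!is.null(layer)) d <- d[d$layer %in% layer, , drop = FALSE]
  # animal-level rows when present, else average the per-section rows
  if (any(is.na(d$section))) d <- d[is.na(d$section), , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for metric ", metric)
  perAnimal <- stats::aggregate(
    d$value, by = c(list(animal = d$animal), lapply(by, function(b) d[[b]])),
    FUN = mean)
  names(perAnimal) <- c("animal", by, "value")
  groups <- unique(perAnimal[, by, drop = FALSE])
  out <- NULL
  for (g in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(perAnimal))
    for (b in by) sel <- sel & perAnimal[[b]] == groups[g, b]
    v <- perAnimal$value[sel]
    if (length(v) == 0) stop("empty group")
    out <- rbind(out, cbind(groups[g, , drop = FALSE],
      data.frame(n = length(v), mean = mean(v),
                 sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA)))
  }
  if (is.null(reference))
    reference <- if ("saline" %in% out[[by[1]]]) "saline" else out[[by[1]]][1]
  out$percentDifference <- NA_real_
  for (g in seq_len(nrow(out))) {
    refSel <- out[[by[1]]] == reference
    for (b in setdiff(by, by[1])) refSel <- refSel & out[[b]] == out[g, b]
    if (!any(refSel)) next
    refMean <- out$mean[refSel][1]
    out$percentDifference[g] <- 100 * (1 - out$mean[g] / refMean)
  }
  rownames(out) <- NULL
  out
}
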