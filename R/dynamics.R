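# Microglia process dynamics on binarized time series: motility index,
# surveillance ratio, and laser-ablation injury convergence.

.asMaskList <- function(masks) {
  lapply(masks, function(m) if (is(m, "BinaryMask")) maskArray(m) else m)
}

#' Motility index of a binarized time series
#'
#' For each consecutive pair of masks (A, B): extended = |B \\ A|,
#' retracted = |A \\ B|, stable = |A intersect B|, and the motility index of
#' the pair is (extended + retracted) / stable. Pairs with no stable pixels
#' are excluded with a warning. No additional change-magnitude threshold is
#' applied beyond the binarization itself.
#'
#' @param masks list of 2-D \linkS4class{BinaryMask} or logical matrices,
#'   ordered in time, equal shapes, length >= 2.
#' @return list(perTransition = numeric vector of per-pair indices,
#'   mean = mean over transitions, pooled = summed changed pixels over
#'   summed stable pixels across all transitions).
#' @export
motilityIndex <- function(masks) {
  ms <- .asMaskList(masks)
  if (length(ms) < 2) stop("need >= 2 timepoints")
  if (length(unique(lapply(ms, dim))) != 1) stop("masks must share one shape")
  nPair <- length(ms) - 1
  mi <- rep(NA_real_, nPair)
  changed <- stable <- numeric(nPair)
  for (i in seq_len(nPair)) {
    A <- ms[[i]]; B <- ms[[i + 1]]
    ext <- sum(B & !A); ret <- sum(A & !B); st <- sum(A & B)
    changed[i] <- ext + ret; stable[i] <- st
    if (st == 0) {
      warning("no stable pixels in transition ", i, "; pair excluded")
    } else {
      mi[i] <- (ext + ret) / st
    }
  }
  ok <- !is.na(mi)
  list(perTransition = mi,
       mean = if (any(ok)) mean(mi[ok]) else NA_real_,
       pooled = if (sum(stable[ok]) > 0)
         sum(changed[ok]) / sum(stable[ok]) else NA_real_)
}

#' Surveillance ratio of a binarized time series
#'
#' The number of pixels in the union (maximum projection over time) of all
#' masks divided by the number of pixels in the first mask. Always >= 1,
#' with equality iff no pixel ever appears outside the first mask.
#'
#' @param masks list of 2-D \linkS4class{BinaryMask} or logical matrices,
#'   ordered in time, length >= 2.
#' @return Single numeric surveillance ratio.
#' @export
surveillanceRatio <- function(masks) {
  ms <- .asMaskList(masks)
  if (length(ms) < 2) stop("need >= 2 timepoints")
  n1 <- sum(ms[[1]])
  if (n1 == 0) stop("first mask is empty")
  un <- Reduce(`|`, ms)
  sum(un) / n1
}

#' Detect the microglia front around an injury core
#'
#' The front is the boundary polygon of the microglia-free connected region
#' that contains the core centroid, computed on a 2-D (max-projected)
#' microglia mask. With no microglia in the frame the front is the image
#' rectangle (with a warning); with microglia touching the core everywhere
#' the front collapses onto the core.
#'
#' @param mask 2-D \linkS4class{BinaryMask} or logical matrix (microglia).
#' @param corePolygon n x 2 matrix (x, y) of the injury-core outline; its
#'   centroid must lie inside the field.
#' @return n x 2 matrix (x, y): the front polygon.
#' @export
detectFront <- function(mask, corePolygon) {
  m <- if (is(mask, "BinaryMask")) maskArray(mask) else mask
  ny <- nrow(m); nx <- ncol(m)
  cen <- colMeans(corePolygon)
  if (cen[1] < 1 || cen[1] > nx || cen[2] < 1 || cen[2] > ny)
    stop("core must lie inside the field")
  # the injury core is autofluorescent debris, not microglia: clear it so
  # the free region between the core and the process tips is connected
  inCore <- .polygonMask(corePolygon, ny, nx)
  m <- m & !inCore
  if (!any(m)) {
    warning("no microglia in frame; front = image rectangle")
    return(cbind(x = c(1, nx, nx, 1), y = c(1, 1, ny, ny)))
  }
  free <- !m
  lab <- labelComponents(free)
  coreLab <- lab[round(cen[2]), round(cen[1])]
  if (coreLab == 0) {
    # centroid pixel occupied by microglia: fall back to the core polygon
    return(corePolygon)
  }
  comp <- lab == coreLab
  dim(comp) <- dim(m)
  # contourLines works on f(x, y) with x = rows; transpose so that contour
  # x/y match image (x, y) pixel coordinates
  cl <- grDevices::contourLines(seq_len(nx), seq_len(ny), t(comp) * 1,
                                levels = 0.5)
  if (!length(cl)) return(corePolygon)
  polys <- lapply(cl, function(p) cbind(x = p$x, y = p$y))
  inside <- vapply(polys, function(p)
    nrow(p) >= 3 && pointsInPolygon(matrix(cen, 1, 2), p), logical(1))
  cand <- polys[inside]
  if (!length(cand)) cand <- polys
  areas <- vapply(cand, polygonArea, numeric(1))
  cand[[which.max(areas)]]
}

#' Injury convergence: normalized front-core proximity over time
#'
#' For each timepoint the core area is subtracted from the front area and
#' the difference normalized to the front-core area of the first timepoint:
#' proximity(t) = (A_front(t) - A_core) / (A_front(1) - A_core). Areas are
#' shoelace polygon areas.
#'
#' @param frontPolygons list (over timepoints, >= 2) of n x 2 (x, y) front
#'   polygons.
#' @param corePolygon n x 2 (x, y) core polygon.
#' @return list(proximity = numeric vector, frontArea, coreArea).
#' @export
injuryConvergence <- function(frontPolygons, corePolygon) {
  if (length(frontPolygons) < 2) stop("need >= 2 timepoints")
  aCore <- polygonArea(corePolygon)
  aFront <- vapply(frontPolygons, polygonArea, numeric(1))
  denom <- aFront[1] - aCore
  if (denom <= 0) stop("degenerate series: first front area equals core area")
  list(proximity = (aFront - aCore) / denom,
       frontArea = aFront, coreArea = aCore)
}
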