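# Spatial statistics on soma coordinates: density per layer ROI,
# nearest-neighbor spacing index, and Purkinje cell linear frequency.

.somaXY <- function(somas) {
  if (is.data.frame(somas)) cbind(somas$x, somas$y) else
    somas[, c(2, 1), drop = FALSE]  # (y, x) matrix input -> (x, y)
}

#' Soma density inside a layer ROI
#'
#' Counts somas whose centroid falls inside the ROI polygon (even-odd rule)
#' and divides by the polygon area in square micrometers.
#'
#' @param somas data.frame with columns x, y (pixel coordinates), e.g. from
#'   \code{\link{detectSomas}} (which returns y, x).
#' @param roi a \linkS4class{LayerROI}.
#' @return list(count, areaUm2, density) with density in somas per um^2.
#' @export
somaDensity <- function(somas, roi) {
  areaUm2 <- roiAreaUm2(roi)
  if (areaUm2 <= 0) stop("zero-area ROI")
  xy <- .somaXY(somas)
  n <- if (nrow(xy) == 0) 0L else sum(pointsInPolygon(xy, roi@polygon))
  list(count = n, areaUm2 = areaUm2, density = n / areaUm2)
}

#' Nearest-neighbor spacing index
#'
#' The square of the mean nearest-neighbor distance multiplied by the
#' density. Dimensionless and invariant to uniform coordinate rescaling:
#' 1.0 for a perfect square grid tiling its area, 0.25 in expectation for a
#' homogeneous 2-D Poisson process (E[NN] = 1 / (2 sqrt(lambda))), and
#' below 0.25 for clustered patterns. Distances are not edge-corrected
#' (a known small-ROI bias).
#'
#' @param somas data.frame with x, y (pixel coordinates), >= 2 rows.
#' @param roi optional \linkS4class{LayerROI}; supplies the area (and
#'   calibration) for the density. Alternatively give \code{areaUm2}.
#' @param areaUm2 area in um^2 when no ROI is given.
#' @param pixelSizeUm calibration for the coordinates when no ROI is given.
#' @return list(meanNNUm, density, spacingIndex).
#' @export
spacingIndex <- function(somas, roi = NULL, areaUm2 = NULL, pixelSizeUm = 1) {
  xy <- .somaXY(somas)
  if (nrow(xy) < 2) stop("spacing index undefined for < 2 somas")
  if (!is.null(roi)) {
    areaUm2 <- roiAreaUm2(roi)
    pixelSizeUm <- roi@pixelSizeUm
  }
  if (is.null(areaUm2)) stop("need roi or areaUm2")
  D <- as.matrix(dist(xy * pixelSizeUm))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  density <- nrow(xy) / areaUm2
  list(meanNNUm = mean(nn), density = density,
       spacingIndex = mean(nn)^2 * density)
}

#' Purkinje cell linear frequency along the PCL path
#'
#' Counts somas lying within a perpendicular band of +/- \code{bandUm}
#' around the PCL polyline and divides by the polyline length. The default
#' band is one soma diameter (16 um).
#'
#' @param somas data.frame with x, y (pixel coordinates).
#' @param pclPath n x 2 matrix (x, y), >= 2 vertices, pixel coordinates.
#' @param bandUm half-width of the assignment band in micrometers.
#' @param pixelSizeUm micrometers per pixel.
#' @return list(count, lengthUm, linearFrequency) with linearFrequency in
#'   somas per micrometer.
#' @export
linearFrequency <- function(somas, pclPath, bandUm = 16, pixelSizeUm = 1) {
  if (nrow(pclPath) < 2) stop("path needs >= 2 vertices")
  lenUm <- polylineLength(pclPath) * pixelSizeUm
  if (lenUm <= 0) stop("zero-length path")
  xy <- .somaXY(somas)
  n <- 0L
  if (nrow(xy) > 0) {
    dPx <- .pointPolylineDist(xy, pclPath)
    n <- sum(dPx * pixelSizeUm <= bandUm)
  }
  list(count = n, lengthUm = lenUm, linearFrequency = n / lenUm)
}

# minimum distance from each point to a polyline (point-to-segment)
.pointPolylineDist <- function(points, path) {
  n <- nrow(path)
  best <- rep(Inf, nrow(points))
  for (i in seq_len(n - 1)) {
    a <- path[i, ]; b <- path[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d <- sqrt((points[, 1] - a[1])^2 + (points[, 2] - a[2])^2)
    } else {
      t <- ((points[, 1] - a[1]) * ab[1] + (points[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
      d <- sqrt((points[, 1] - px)^2 + (points[, 2] - py)^2)
    }
    best <- pmin(best, d)
  }
  best
}
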