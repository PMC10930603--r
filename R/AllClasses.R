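#' @import methods
#' @importFrom stats fft lm coef glm poisson rnorm runif rpois sd quantile setNames mvfft optimize dist
#' @importFrom utils head tail write.csv read.csv
#' @importFrom Rcpp sourceCpp
#' @useDynLib gliaquant, .registration = TRUE
NULL

#' TimelapseStack: calibrated multi-channel image time series
#'
#' Container for a 5-D fluorescence image indexed \code{[time, z, channel,
#' y, x]}, with voxel calibration in micrometers and the imaging interval in
#' minutes. Channel 1 is the microglia (GFP) channel and channel 2 the
#' Purkinje cell (tdTomato) channel by convention; labels are carried in
#' \code{channels}.
#'
#' @slot data numeric array, dim (time, z, channel, y, x), intensities >= 0.
#' @slot voxelSizeUm named numeric, micrometers per voxel along y, x, z.
#' @slot dtMin numeric, minutes between timepoints.
#' @slot channels character vector of channel labels.
#' @export
setClass("TimelapseStack",
  representation(data = "array", voxelSizeUm = "numeric",
                 dtMin = "numeric", channels = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 5L)
      return("data must be a 5-D array (time, z, channel, y, x)")
    if (d[3] != length(object@channels))
      return("number of channels does not match channel labels")
    if (!all(c("y", "x", "z") %in% names(object@voxelSizeUm)))
      return("voxelSizeUm must be named with y, x, z")
    if (any(object@voxelSizeUm <= 0)) return("voxel sizes must be positive")
    if (min(object@data) < 0) return("intensities must be non-negative")
    TRUE
  })

#' Construct a TimelapseStack
#'
#' @param data 5-D array (time, z, channel, y, x).
#' @param voxelSizeUm named numeric c(y=, x=, z=) in micrometers.
#' @param dtMin minutes between timepoints.
#' @param channels channel labels.
#' @return A \linkS4class{TimelapseStack}.
#' @export
TimelapseStack <- function(data, voxelSizeUm = c(y = 1, x = 1, z = 1),
                           dtMin = 5, channels = c("microglia", "purkinje")) {
  new("TimelapseStack", data = data, voxelSizeUm = voxelSizeUm,
      dtMin = dtMin, channels = channels)
}

#' @describeIn TimelapseStack-class number of timepoints
#' @param x a TimelapseStack
#' @export
nTimepoints <- function(x) dim(x@data)[1]

#' @describeIn TimelapseStack-class stack dimensions (time, z, channel, y, x)
#' @export
stackDim <- function(x) dim(x@data)

#' @describeIn TimelapseStack-class voxel calibration (micrometers)
#' @export
voxelSize <- function(x) x@voxelSizeUm

#' Extract one frame of a stack
#'
#' @param x a \linkS4class{TimelapseStack}.
#' @param t timepoint index.
#' @param channel channel index or label.
#' @param z optional z index; if missing, the full (z, y, x) array is
#'   returned, else a (y, x) matrix.
#' @return numeric array.
#' @export
getFrame <- function(x, t, channel, z = NULL) {
  if (is.character(channel)) channel <- match(channel, x@channels)
  d <- dim(x@data)
  if (is.null(z)) {
    out <- x@data[t, , channel, , , drop = FALSE]
    array(out, dim = d[c(2, 4, 5)])
  } else {
    matrix(x@data[t, z, channel, , ], d[4], d[5])
  }
}

setMethod("show", "TimelapseStack", function(object) {
  d <- dim(object@data)
  cat("TimelapseStack:", d[1], "timepoints x", d[2], "z x",
      d[3], "channels x", d[4], "x", d[5], "px\n")
  cat("  channels:", paste(object@channels, collapse = ", "), "\n")
  cat("  voxel (um):", paste(sprintf("%s=%g", names(object@voxelSizeUm),
                                     object@voxelSizeUm), collapse = " "),
      " dt:", object@dtMin, "min\n")
})

#' BinaryMask: thresholded object mask for one cell class
#'
#' @slot mask logical array, 2-D (y, x) or 3-D (y, x, z).
#' @slot pixelSizeUm numeric, micrometers per pixel (y/x; isotropic in-plane).
#' @slot label character, cell-class label (e.g. "microglia").
#' @export
setClass("BinaryMask",
  representation(mask = "array", pixelSizeUm = "numeric", label = "character"),
  validity = function(object) {
    nd <- length(dim(object@mask))
    if (!nd %in% c(2L, 3L)) return("mask must be 2-D or 3-D")
    if (!is.logical(object@mask)) return("mask must be logical")
    TRUE
  })

#' Construct a BinaryMask
#' @param mask logical matrix or 3-D array; numeric input is coerced via > 0.
#' @param pixelSizeUm micrometers per in-plane pixel.
#' @param label cell-class label.
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(mask, pixelSizeUm = 1, label = "object") {
  if (!is.logical(mask)) {
    storage <- mask > 0
    dim(storage) <- dim(mask)
    mask <- storage
  }
  if (is.null(dim(mask))) stop("mask must have dimensions")
  new("BinaryMask", mask = mask, pixelSizeUm = pixelSizeUm, label = label)
}

#' @describeIn BinaryMask-class the logical array
#' @param x a BinaryMask
#' @export
maskArray <- function(x) x@mask

#' @describeIn BinaryMask-class number of foreground pixels
#' @export
maskSize <- function(x) sum(x@mask)

setMethod("show", "BinaryMask", function(object) {
  cat("BinaryMask [", object@label, "]: ",
      paste(dim(object@mask), collapse = " x "), " px, ",
      sum(object@mask), " foreground\n", sep = "")
})

#' LayerROI: labeled layer polygon with calibrated area
#'
#' A polygon region of interest delimiting one cerebellar layer (ML+PCL
#' combined, GL, or WM) in pixel coordinates, with in-plane calibration.
#'
#' @slot label character, one of "ML_PCL", "GL", "WM" (or any user label).
#' @slot polygon numeric matrix, n x 2, columns (x, y) in pixel coordinates.
#' @slot pixelSizeUm micrometers per pixel.
#' @export
setClass("LayerROI",
  representation(label = "character", polygon = "matrix",
                 pixelSizeUm = "numeric"),
  validity = function(object) {
    if (ncol(object@polygon) != 2) return("polygon must be n x 2 (x, y)")
    if (nrow(object@polygon) < 3) return("polygon needs >= 3 vertices")
    if (.selfIntersects(object@polygon))
      return("polygon must be non-self-intersecting")
    if (abs(polygonArea(object@polygon)) <= 0) return("area must be > 0")
    TRUE
  })

#' Construct a LayerROI
#' @param label layer label.
#' @param polygon n x 2 matrix of (x, y) vertices, pixel coordinates.
#' @param pixelSizeUm micrometers per pixel.
#' @return A \linkS4class{LayerROI}.
#' @export
LayerROI <- function(label, polygon, pixelSizeUm = 1) {
  new("LayerROI", label = label, polygon = polygon, pixelSizeUm = pixelSizeUm)
}

#' @describeIn LayerROI-class polygon area in square micrometers
#' @param x a LayerROI
#' @export
roiAreaUm2 <- function(x) polygonArea(x@polygon) * x@pixelSizeUm^2

setMethod("show", "LayerROI", function(object) {
  cat("LayerROI [", object@label, "]: ", nrow(object@polygon),
      " vertices, area ", signif(roiAreaUm2(object), 5), " um^2\n", sep = "")
})

# segment-crossing test used by the LayerROI validity method
.selfIntersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  seg <- cbind(poly, rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]))
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # shared vertex with closing edge
      p1 <- seg[i, 1:2]; p2 <- seg[i, 3:4]
      p3 <- seg[j, 1:2]; p4 <- seg[j, 3:4]
      d1 <- cross(p3, p4, p1); d2 <- cross(p3, p4, p2)
      d3 <- cross(p1, p2, p3); d4 <- cross(p1, p2, p4)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}
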