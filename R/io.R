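# I/O: multi-page TIFF (pages ordered T, then Z, then C) with a JSON
# sidecar carrying dimensions and calibration; ROI polygons and paths as
# JSON; masks as 8-bit TIFF.

#' Write a TimelapseStack as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered timepoint-major, then z, then channel (TZCYX).
#' Intensities are stored 16-bit after scaling by the stack maximum; the
#' scale, dimensions, calibration, and channel labels go to
#' \code{<path>.json}.
#'
#' @param stack a \linkS4class{TimelapseStack}.
#' @param path output TIFF path.
#' @return Invisibly, the sidecar path.
#' @export
writeTimelapseTiff <- function(stack, path) {
  d <- dim(stack@data)
  scale <- max(stack@data, 1)
  pages <- vector("list", d[1] * d[2] * d[3])
  k <- 0
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (c in seq_len(d[3])) {
    k <- k + 1
    pages[[k]] <- matrix(stack@data[t, z, c, , ], d[4], d[5]) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(
    dim = d, order = "TZCYX", scale = scale,
    voxelSizeUm = as.list(stack@voxelSizeUm), dtMin = stack@dtMin,
    channels = stack@channels), side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a TimelapseStack written by \code{writeTimelapseTiff}
#'
#' @param path TIFF path (sidecar expected at \code{<path>.json}).
#' @return A \linkS4class{TimelapseStack}.
#' @export
readTimelapseTiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  data <- array(0, dim = d)
  k <- 0
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (c in seq_len(d[3])) {
    k <- k + 1
    data[t, z, c, , ] <- pages[[k]] * meta$scale
  }
  TimelapseStack(data, voxelSizeUm = unlist(meta$voxelSizeUm),
                 dtMin = meta$dtMin, channels = meta$channels)
}

#' Write layer ROIs (and optionally a PCL path) as JSON
#'
#' Polygons are stored as lists of (x, y) vertices in pixel coordinates.
#'
#' @param rois list of \linkS4class{LayerROI}.
#' @param path output JSON path.
#' @param pclPath optional n x 2 (x, y) polyline.
#' @return Invisibly, \code{path}.
#' @export
writeRoiJson <- function(rois, path, pclPath = NULL) {
  out <- list(rois = lapply(rois, function(r) list(
    label = r@label, pixelSizeUm = r@pixelSizeUm,
    polygon = unname(apply(r@polygon, 1, as.list)))))
  if (!is.null(pclPath))
    out$pclPath <- unname(apply(pclPath, 1, as.list))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read layer ROIs written by \code{writeRoiJson}
#'
#' @param path JSON path.
#' @return list(rois = list of \linkS4class{LayerROI}, pclPath = matrix or
#'   NULL).
#' @export
readRoiJson <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rois <- lapply(raw$rois, function(r) {
    poly <- do.call(rbind, lapply(r$polygon, function(v)
      c(v[[1]], v[[2]])))
    colnames(poly) <- c("x", "y")
    LayerROI(r$label, poly, r$pixelSizeUm)
  })
  names(rois) <- vapply(rois, function(r) r@label, character(1))
  pclPath <- NULL
  if (!is.null(raw$pclPath)) {
    pclPath <- do.call(rbind, lapply(raw$pclPath, function(v)
      c(v[[1]], v[[2]])))
    colnames(pclPath) <- c("x", "y")
  }
  list(rois = rois, pclPath = pclPath)
}

#' Write a BinaryMask as 8-bit TIFF (one page per z-slice)
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMaskTiff <- function(mask, path) {
  m <- maskArray(mask)
  if (length(dim(m)) == 2) {
    tiff::writeTIFF(m * 1, path, bits.per.sample = 8)
  } else {
    pages <- lapply(seq_len(dim(m)[3]), function(z) m[, , z] * 1)
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
  }
  invisible(path)
}
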