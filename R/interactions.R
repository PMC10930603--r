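# Microglia-Purkinje cell interactions: volume fractions, 3-D overlap,
# normalized interaction, and the dynamic interaction / coverage indices on
# max-projected interaction masks.

#' Volume fraction of a mask within a region
#'
#' Foreground voxels divided by the region volume in voxels.
#'
#' @param mask \linkS4class{BinaryMask} or logical array.
#' @param regionVoxels region volume in voxels; defaults to the full mask
#'   extent. May also be a logical array selecting the region.
#' @return Dimensionless fraction in [0, 1].
#' @export
volumeFraction <- function(mask, regionVoxels = NULL) {
  m <- if (is(mask, "BinaryMask")) maskArray(mask) else mask
  if (is.null(regionVoxels)) {
    return(sum(m) / length(m))
  }
  if (is.array(regionVoxels) || is.matrix(regionVoxels)) {
    v <- sum(regionVoxels)
    if (v == 0) stop("zero region")
    return(sum(m & regionVoxels) / v)
  }
  if (regionVoxels == 0) stop("zero region")
  sum(m) / regionVoxels
}

#' Voxelwise overlap of two masks
#'
#' The interaction mask is the voxelwise AND of the binarized microglia and
#' Purkinje images (equivalent to multiplying the binarized images).
#'
#' @param microglia,purkinje \linkS4class{BinaryMask} or logical arrays of
#'   equal shape.
#' @return list(mask = BinaryMask of the overlap, count = voxel count).
#' @export
interactionOverlap <- function(microglia, purkinje) {
  a <- if (is(microglia, "BinaryMask")) maskArray(microglia) else microglia
  b <- if (is(purkinje, "BinaryMask")) maskArray(purkinje) else purkinje
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  ov <- a & b
  px <- if (is(microglia, "BinaryMask")) microglia@pixelSizeUm else 1
  list(mask = BinaryMask(ov, px, "interaction"), count = sum(ov))
}

#' Normalized microglia-Purkinje interaction
#'
#' Overlap voxels normalized to microglia voxels, averaged over timepoints
#' (in vivo) or sections (fixed). Entries with an empty microglia mask are
#' excluded with a warning. Applies identically to whole-cell and
#' subcomponent mask pairs.
#'
#' @param overlapCounts numeric vector of overlap voxel counts per
#'   timepoint/section.
#' @param microgliaCounts matching vector of microglia voxel counts.
#' @return list(perTimepoint = ratios, mean = average over valid entries).
#' @export
normalizedInteraction <- function(overlapCounts, microgliaCounts) {
  stopifnot(length(overlapCounts) == length(microgliaCounts))
  ratio <- rep(NA_real_, length(overlapCounts))
  ok <- microgliaCounts > 0
  if (!all(ok))
    warning(sum(!ok), " timepoint(s) with empty microglia mask excluded")
  ratio[ok] <- overlapCounts[ok] / microgliaCounts[ok]
  list(perTimepoint = ratio,
       mean = if (any(ok)) mean(ratio[ok]) else NA_real_)
}

#' Dynamic interaction index
#'
#' The motility-index formula applied to the (max-projected) interaction
#' mask sequence: extended plus retracted interaction pixels divided by
#' stable interaction pixels, per consecutive pair, averaged.
#'
#' @param interactionMasks list of 2-D masks over time (>= 2).
#' @return As \code{\link{motilityIndex}}.
#' @export
dynamicInteractionIndex <- function(interactionMasks) {
  motilityIndex(interactionMasks)
}

#' Interaction coverage index
#'
#' Union of interaction pixels over all timepoints divided by the total
#' frame pixel count, on max-projected frames.
#'
#' @param interactionMasks list of 2-D masks over time (>= 1).
#' @return Dimensionless fraction in [0, 1].
#' @export
coverageIndex <- function(interactionMasks) {
  ms <- .asMaskList(interactionMasks)
  if (length(ms) < 1) stop("need >= 1 timepoint")
  un <- Reduce(`|`, ms)
  sum(un) / length(un)
}
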