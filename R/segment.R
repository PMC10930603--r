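# Deterministic surrogates for learned pixel classifiers: thresholding with
# size exclusion, soma detection, and subcomponent classification by
# morphology. Masks are (y, x) or (y, x, z).

# per-slice morphological opening with a disc brush (odd-sized)
.openDisc <- function(mask, radius) {
  if (radius < 1) return(mask)
  brush <- EBImage::makeBrush(2L * floor(radius) + 1L, shape = "disc")
  op <- function(m) EBImage::opening(m * 1, brush) > 0.5
  d <- dim(mask)
  if (length(d) == 2) return(op(mask))
  out <- mask
  for (z in seq_len(d[3])) out[, , z] <- op(mask[, , z])
  out
}

.dilateDisc <- function(mask, radius) {
  if (radius < 1) return(mask)
  brush <- EBImage::makeBrush(2L * floor(radius) + 1L, shape = "disc")
  dl <- function(m) EBImage::dilate(m * 1, brush) > 0.5
  d <- dim(mask)
  if (length(d) == 2) return(dl(mask))
  out <- mask
  for (z in seq_len(d[3])) out[, , z] <- dl(mask[, , z])
  out
}

#' Binarize objects with threshold and size exclusion
#'
#' Foreground is every pixel with intensity >= \code{threshold}; connected
#' components (8-connectivity in 2-D, 26-connectivity in 3-D) whose size is
#' outside [\code{minSize}, \code{maxSize}] are removed. Raising the
#' threshold never adds foreground before size filtering.
#'
#' @param image numeric array, (y, x) or (y, x, z).
#' @param threshold intensity threshold.
#' @param minSize,maxSize component size bounds in pixels
#'   (default: no exclusion).
#' @param pixelSizeUm in-plane calibration carried into the mask.
#' @param label cell-class label.
#' @return A \linkS4class{BinaryMask}.
#' @export
binarizeObjects <- function(image, threshold, minSize = 1, maxSize = Inf,
                            pixelSizeUm = 1, label = "object") {
  stopifnot(minSize > 0, minSize <= maxSize)
  mask <- image >= threshold
  dim(mask) <- dim(image)
  if (minSize > 1 || is.finite(maxSize)) {
    lab <- labelComponents(mask)
    nmax <- attr(lab, "max")
    if (nmax > 0) {
      sizes <- tabulate(lab[lab > 0], nbins = nmax)
      drop <- which(sizes < minSize | sizes > maxSize)
      if (length(drop)) mask[lab %in% drop] <- FALSE
    }
  }
  BinaryMask(mask, pixelSizeUm = pixelSizeUm, label = label)
}

#' Detect somas as size-filtered components after opening
#'
#' Morphological opening with a disc of radius \code{openRadius} removes
#' thin processes; remaining connected components within the size bounds are
#' reported with their centroids.
#'
#' @param x a \linkS4class{BinaryMask} or logical array.
#' @param somaMinSize,somaMaxSize component size bounds (pixels) after
#'   opening.
#' @param openRadius disc radius (px) of the opening.
#' @return data.frame with columns y, x (and z for 3-D input) and size;
#'   one row per soma.
#' @export
detectSomas <- function(x, somaMinSize = 10, somaMaxSize = Inf,
                        openRadius = 2) {
  stopifnot(somaMinSize > 0, somaMinSize <= somaMaxSize)
  mask <- if (is(x, "BinaryMask")) maskArray(x) else x
  opened <- .openDisc(mask, openRadius)
  lab <- labelComponents(opened)
  nmax <- attr(lab, "max")
  nd <- length(dim(mask))
  empty <- if (nd == 3)
    data.frame(y = numeric(0), x = numeric(0), z = numeric(0),
               size = integer(0))
  else data.frame(y = numeric(0), x = numeric(0), size = integer(0))
  if (nmax == 0) return(empty)
  sizes <- tabulate(lab[lab > 0], nbins = nmax)
  keep <- which(sizes >= somaMinSize & sizes <= somaMaxSize)
  if (!length(keep)) return(empty)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  sel <- labs %in% keep
  idx <- idx[sel, , drop = FALSE]; labs <- labs[sel]
  cen <- rowsum(idx * 1, labs) / as.vector(table(labs))
  out <- data.frame(y = cen[, 1], x = cen[, 2])
  if (nd == 3) out$z <- cen[, 3]
  out$size <- sizes[sort(keep)]
  out
}

#' Split a microglia mask into soma and process masks
#'
#' Soma pixels are those surviving a morphological opening with a disc of
#' radius \code{rSoma}; everything else in the mask is process. The two
#' outputs partition the input exactly.
#'
#' @param mask a \linkS4class{BinaryMask} (microglia).
#' @param rSoma opening disc radius in pixels (default 3).
#' @return list(soma = BinaryMask, process = BinaryMask).
#' @export
classifySubcomponents <- function(mask, rSoma = 3) {
  m <- maskArray(mask)
  if (!any(m)) stop("empty mask")
  soma <- .openDisc(m, rSoma)
  if (!any(soma))
    warning("opening removed everything: no soma pixels, all process")
  proc <- m & !soma
  list(soma = BinaryMask(soma, mask@pixelSizeUm, "microglia_soma"),
       process = BinaryMask(proc, mask@pixelSizeUm, "microglia_process"))
}

#' Classify Purkinje cell components
#'
#' In the ML the mask is skeletonized (Zhang-Suen thinning); skeleton pixels
#' with >= 3 skeleton neighbors are branch points, dilated to
#' \code{branchRadius}; the rest of the mask is dendrite. In the PCL, somas
#' are detected with \code{\link{detectSomas}}.
#'
#' @param mask a \linkS4class{BinaryMask} (Purkinje channel); 2-D for ML.
#' @param layer "ML" or "PCL".
#' @param branchRadius dilation radius for branch-point markers (px).
#' @param ... passed to \code{\link{detectSomas}} for layer "PCL".
#' @return For "ML": list(dendrite, branch, skeleton = BinaryMasks,
#'   nBranchPoints = count of branch-point clusters). For "PCL":
#'   list(somas = data.frame).
#' @export
classifyPurkinjeComponents <- function(mask, layer = c("ML", "PCL"),
                                       branchRadius = 2, ...) {
  layer <- match.arg(layer)
  m <- maskArray(mask)
  if (layer == "PCL") return(list(somas = detectSomas(mask, ...)))
  if (length(dim(m)) == 3) m <- maxProject(m)
  skel <- .skeletonizeC(m)
  # neighbor count on the skeleton (8-connectivity)
  nb <- matrix(0L, nrow(skel), ncol(skel))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- nb + .shift2d(skel * 1L, dy, dx)
  }
  junction <- skel & nb >= 3
  nBranch <- if (any(junction)) attr(labelComponents(junction), "max") else 0L
  branch <- m & .dilateDisc(junction, branchRadius)
  dendrite <- m & !branch
  px <- mask@pixelSizeUm
  list(dendrite = BinaryMask(dendrite, px, "purkinje_dendrite"),
       branch = BinaryMask(branch, px, "purkinje_branch"),
       skeleton = BinaryMask(skel, px, "purkinje_skeleton"),
       nBranchPoints = nBranch)
}
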