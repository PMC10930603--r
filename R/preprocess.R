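# Preprocessing of time-lapse stacks: blinding, drift correction,
# bleed-through estimation and subtraction, temporal PCA denoising, layer
# substacks, maximum projection.

#' Blind a set of image files
#'
#' Assigns opaque identifiers to file paths in a random order so that
#' downstream analysis is blind to group membership; the key table recovers
#' the original names.
#'
#' @param paths character vector of file paths (must be unique).
#' @param seed integer seed controlling the permutation.
#' @param keyFile optional path; if given the key table is written as CSV.
#' @return data.frame with columns \code{blindId} and \code{original},
#'   ordered by blind id.
#' @export
blindDataset <- function(paths, seed, keyFile = NULL) {
  if (length(paths) < 1) stop("need at least one path")
  if (anyDuplicated(paths)) stop("duplicate paths")
  set.seed(as.integer(seed))
  perm <- sample(length(paths))
  key <- data.frame(
    blindId = sprintf("blind_%03d", seq_along(paths)),
    original = paths[perm],
    stringsAsFactors = FALSE)
  if (!is.null(keyFile)) write.csv(key, keyFile, row.names = FALSE)
  key
}

# integer-pixel translation estimate by FFT cross-correlation; returns the
# (dy, dx) by which `img` is shifted relative to `ref`
.xcorrShift <- function(ref, img) {
  ny <- nrow(ref); nx <- ncol(ref)
  a <- ref - mean(ref); b <- img - mean(img)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  k <- which.max(cc)
  dy <- (k - 1) %% ny; dx <- (k - 1) %/% ny
  # cross-correlation peak at (-dy, -dx) modulo N
  dy <- -dy; dx <- -dx
  if (dy < -ny / 2) dy <- dy + ny
  if (dx < -nx / 2) dx <- dx + nx
  c(dy = dy, dx = dx)
}

#' Correct lateral drift of a time-lapse stack
#'
#' Estimates a per-timepoint integer (y, x) translation of the
#' microglia-channel maximum projection against timepoint 1 by FFT
#' cross-correlation, and shifts every z-slice and channel back, padding
#' with zeros. Registration is idempotent: a corrected stack yields zero
#' offsets.
#'
#' @param stack a \linkS4class{TimelapseStack} with >= 2 timepoints.
#' @param channel channel used for estimation (default "microglia").
#' @return list(stack = corrected stack, drift = T x 2 integer matrix of the
#'   estimated (dy, dx) offsets relative to timepoint 1).
#' @export
correctDrift <- function(stack, channel = "microglia") {
  d <- dim(stack@data)
  nT <- d[1]
  if (nT < 2) stop("need >= 2 timepoints")
  ch <- match(channel, stack@channels)
  proj <- lapply(seq_len(nT), function(t)
    maxProject(getFrame(stack, t, ch)))
  ref <- proj[[1]]
  drift <- matrix(0L, nT, 2, dimnames = list(NULL, c("dy", "dx")))
  for (t in 2:nT) {
    if (all(proj[[t]] == 0)) {
      warning("all-zero frame at timepoint ", t, "; offset set to (0,0)")
      next
    }
    drift[t, ] <- as.integer(.xcorrShift(ref, proj[[t]]))
  }
  out <- stack@data
  for (t in 2:nT) {
    if (all(drift[t, ] == 0)) next
    for (z in seq_len(d[2])) for (c in seq_len(d[3]))
      out[t, z, c, , ] <- .shift2d(matrix(stack@data[t, z, c, , ], d[4], d[5]),
                                   -drift[t, 1], -drift[t, 2])
  }
  corrected <- stack
  corrected@data <- out
  list(stack = corrected, drift = drift)
}

#' Estimate channel bleed-through
#'
#' The bleed fraction alpha is the least-squares slope of microglia-channel
#' intensity against Purkinje-channel intensity over pixels that carry
#' Purkinje signal but no microglia signal (the intercept absorbs
#' background). Doubling the Purkinje emission leaves alpha unchanged.
#'
#' @param stack a \linkS4class{TimelapseStack}.
#' @param purkinjeOnlyMask logical array (z, y, x) or voxel index vector
#'   selecting Purkinje-only voxels (e.g. from ground truth or a user ROI).
#' @param t timepoint used (default 1).
#' @return list(alpha = estimated bleed fraction).
#' @export
estimateBleedthrough <- function(stack, purkinjeOnlyMask, t = 1) {
  mg <- getFrame(stack, t, "microglia")
  pk <- getFrame(stack, t, "purkinje")
  sel <- if (is.logical(purkinjeOnlyMask)) which(purkinjeOnlyMask) else
    as.integer(purkinjeOnlyMask)
  if (length(sel) == 0) stop("empty Purkinje-only mask")
  fit <- lm(mg[sel] ~ pk[sel])
  list(alpha = max(0, unname(coef(fit)[2])))
}

#' Subtract channel bleed-through
#'
#' Each frame of each channel is first corrected for background (the modal
#' intensity of the frame), then the brightness-compensated Purkinje channel
#' is subtracted from the microglia channel and the result clipped at zero.
#'
#' @param stack a \linkS4class{TimelapseStack}.
#' @param alpha bleed fraction (e.g. from \code{estimateBleedthrough}).
#' @return The corrected \linkS4class{TimelapseStack}.
#' @export
subtractBleedthrough <- function(stack, alpha) {
  d <- dim(stack@data)
  out <- stack@data
  chM <- match("microglia", stack@channels)
  chP <- match("purkinje", stack@channels)
  for (t in seq_len(d[1])) {
    for (c in seq_len(d[3])) {
      fr <- out[t, , c, , ]
      bg <- .frameMode(fr)
      out[t, , c, , ] <- pmax(0, fr - bg)
    }
    out[t, , chM, , ] <- pmax(0, out[t, , chM, , ] - alpha * out[t, , chP, , ])
  }
  stack@data <- out
  stack
}

#' Temporal PCA denoising
#'
#' Treats the timepoints of each channel as observations and voxels as
#' variables, and reconstructs the stack from the mean image plus the top-k
#' temporal principal components. With k equal to the number of timepoints
#' the input is recovered (within floating point).
#'
#' @param stack a \linkS4class{TimelapseStack}.
#' @param k number of components to keep (>= 1).
#' @return The denoised \linkS4class{TimelapseStack}.
#' @export
pcaDenoise <- function(stack, k) {
  d <- dim(stack@data)
  nT <- d[1]
  if (k < 1) stop("k must be >= 1")
  if (k > nT) {
    warning("k exceeds the number of timepoints; returning input unchanged")
    return(stack)
  }
  out <- stack@data
  for (c in seq_len(d[3])) {
    X <- matrix(stack@data[, , c, , ], nrow = nT)  # T x (z*y*x)
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    S <- tcrossprod(Xc)                            # T x T
    eg <- eigen(S, symmetric = TRUE)
    U <- eg$vectors[, seq_len(k), drop = FALSE]
    Xhat <- U %*% (t(U) %*% Xc)
    Xhat <- sweep(Xhat, 2, mu, `+`)
    out[, , c, , ] <- array(pmax(0, Xhat), dim = d[c(1, 2, 4, 5)])
  }
  stack@data <- out
  stack
}

#' Split a stack into ML and PCL substacks
#'
#' The ML substack takes \code{nSlices} z-slices ending at \code{pclStartZ}
#' (exclusive) and the PCL substack \code{nSlices} starting at
#' \code{pclStartZ} (inclusive); both substacks always have the same depth.
#' Indices are 1-based; the intervals are half-open:
#' ML = [pclStartZ - nSlices, pclStartZ), PCL = [pclStartZ,
#' pclStartZ + nSlices).
#'
#' @param stack a \linkS4class{TimelapseStack}.
#' @param pclStartZ 1-based z index of the first PCL slice.
#' @param nSlices number of slices per substack.
#' @return list(ML = substack, PCL = substack).
#' @export
splitLayers <- function(stack, pclStartZ, nSlices) {
  nz <- dim(stack@data)[2]
  if (pclStartZ + nSlices - 1 > nz || pclStartZ - nSlices < 1)
    stop("layer slice range out of bounds")
  mlIdx <- seq(pclStartZ - nSlices, pclStartZ - 1)
  pclIdx <- seq(pclStartZ, pclStartZ + nSlices - 1)
  sub <- function(idx) {
    s <- stack
    s@data <- stack@data[, idx, , , , drop = FALSE]
    s
  }
  list(ML = sub(mlIdx), PCL = sub(pclIdx))
}

#' Maximum intensity projection over z
#'
#' @param x a (z, y, x) numeric array (e.g. from \code{getFrame}), a
#'   (y, x, z) logical mask array, or a \linkS4class{TimelapseStack}
#'   (projected per timepoint and channel).
#' @param zAxis which array dimension is z. Default: 1 for numeric 3-D
#'   arrays (the \code{getFrame} layout) and 3 for logical masks (the
#'   \linkS4class{BinaryMask} layout); pass it explicitly for anything else.
#' @return For an array, the (y, x) per-pixel maximum over z; for a stack, a
#'   list over timepoints of lists over channels of 2-D images.
#' @export
maxProject <- function(x, zAxis = NULL) {
  if (is(x, "TimelapseStack")) {
    d <- dim(x@data)
    return(lapply(seq_len(d[1]), function(t)
      setNames(lapply(seq_len(d[3]), function(c)
        maxProject(getFrame(x, t, c), zAxis = 1)), x@channels)))
  }
  d <- dim(x)
  if (length(d) == 2) return(x)
  stopifnot(length(d) == 3)
  if (is.null(zAxis)) zAxis <- if (is.logical(x)) 3L else 1L
  if (zAxis != 3L) x <- aperm(x, c(setdiff(1:3, zAxis), zAxis))
  d <- dim(x)
  if (is.logical(x)) {
    out <- x[, , 1]
    for (z in seq_len(d[3])[-1]) out <- out | x[, , z]
    return(out)
  }
  out <- matrix(x[, , 1], d[1], d[2])
  for (z in seq_len(d[3])[-1]) out <- pmax(out, matrix(x[, , z], d[1], d[2]))
  out
}
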