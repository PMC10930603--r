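#' Polygon area by the shoelace formula
#'
#' @param poly n x 2 matrix of (x, y) vertices (open or closed ring).
#' @return Absolute enclosed area in squared input units.
#' @export
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n] }
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Point-in-polygon test (even-odd rule)
#'
#' Thin wrapper around \code{mgcv::in.out}; points exactly on an edge follow
#' that routine's even-odd convention.
#'
#' @param points n x 2 matrix (x, y).
#' @param poly m x 2 polygon matrix (x, y).
#' @return Logical vector of length n.
#' @export
pointsInPolygon <- function(points, poly) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 2)
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, points)
}

#' Length of a polyline
#'
#' @param path n x 2 matrix of (x, y) vertices.
#' @return Sum of Euclidean segment lengths.
#' @export
polylineLength <- function(path) {
  d <- diff(path)
  sum(sqrt(rowSums(d^2)))
}

# Ordered pixel ring: Bresenham/midpoint circle rasterization, points sorted
# by angle so that foreground runs can be counted along the circle.
.rasterCircle <- function(radiusPx) {
  r <- round(radiusPx)
  if (r < 1) return(matrix(numeric(0), 0, 2))
  x <- 0L; y <- r; d <- 3L - 2L * r
  pts <- matrix(0L, 0, 2)
  while (x <= y) {
    pts <- rbind(pts,
      c(x, y), c(y, x), c(y, -x), c(x, -y),
      c(-x, -y), c(-y, -x), c(-y, x), c(-x, y))
    if (d < 0) d <- d + 4L * x + 6L else { d <- d + 4L * (x - y) + 10L; y <- y - 1L }
    x <- x + 1L
  }
  pts <- unique(pts)
  pts[order(atan2(pts[, 2], pts[, 1])), , drop = FALSE]
}

# integer 2-D shift with zero fill; positive dy shifts content down (larger y)
.shift2d <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0, ny, nx)
  ys <- seq_len(ny); xs <- seq_len(nx)
  ysrc <- ys - dy; xsrc <- xs - dx
  okY <- ysrc >= 1 & ysrc <= ny; okX <- xsrc >= 1 & xsrc <= nx
  out[ys[okY], xs[okX]] <- m[ysrc[okY], xsrc[okX]]
  out
}

# modal intensity of a frame, on integer-rounded values
.frameMode <- function(v) {
  tb <- tabulate(as.integer(round(v)) + 1L)
  which.max(tb) - 1L
}

# draw a filled disc into a logical matrix, returning pixel indices
.discPixels <- function(cy, cx, r, ny, nx) {
  ys <- max(1, floor(cy - r)):min(ny, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(nx, ceiling(cx + r))
  g <- expand.grid(y = ys, x = xs)
  keep <- (g$y - cy)^2 + (g$x - cx)^2 <= r^2
  cbind(y = g$y[keep], x = g$x[keep])
}

# Bresenham line pixels between two integer points (inclusive)
.linePixels <- function(y0, x0, y1, x1) {
  dy <- abs(y1 - y0); dx <- abs(x1 - x0)
  sy <- ifelse(y0 < y1, 1L, -1L); sx <- ifelse(x0 < x1, 1L, -1L)
  err <- dx - dy
  y <- y0; x <- x0
  out <- matrix(0L, dx + dy + 1L, 2)
  k <- 0L
  repeat {
    k <- k + 1L
    out[k, ] <- c(y, x)
    if (y == y1 && x == x1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  out[seq_len(k), , drop = FALSE]
}

#' Label connected components of a mask
#'
#' 8-connectivity in 2-D, 26-connectivity in 3-D.
#'
#' @param mask logical array (2-D or 3-D) or \linkS4class{BinaryMask}.
#' @return Integer array of the same shape; 0 is background, components are
#'   numbered 1..n; attribute \code{max} holds n.
#' @export
labelComponents <- function(mask) {
  if (is(mask, "BinaryMask")) mask <- maskArray(mask)
  .labelComponentsC(as.logical(mask), as.integer(dim(mask)))
}
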