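# Shared fixtures: small synthetic datasets are generated once per test run
# and memoized here, since several test files interrogate the same stacks.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(key, fun) {
  if (!exists(key, envir = .fixtureCache)) assign(key, fun(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(imageShape = c(y = 64L, x = 64L, z = 24L),
                   nTimepoints = 6L, drift = 0, noiseSd = 0,
                   bleedAlpha = 0, backgroundLevel = 0, seed = 101L)
  do.call(synthConfig, utils::modifyList(defaults, args))
}

cleanTimelapse <- function() memoFixture("cleanTimelapse", function()
  generateTimelapse(smallConfig(processTurnover = 0.1)))

# brute-force oracles, written independently of the package internals

oracleMotility <- function(A, B) {
  ext <- 0; ret <- 0; st <- 0
  for (i in seq_along(A)) {
    if (A[i] && B[i]) st <- st + 1
    else if (A[i] && !B[i]) ret <- ret + 1
    else if (!A[i] && B[i]) ext <- ext + 1
  }
  (ext + ret) / st
}

oracleUnionCount <- function(masks) {
  u <- masks[[1]]
  for (m in masks[-1]) u <- u | m
  sum(u)
}

oracleShoelace <- function(xy) {
  n <- nrow(xy); s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + xy[i, 1] * xy[j, 2] - xy[j, 1] * xy[i, 2]
  }
  unname(abs(s) / 2)
}

oracleRayCast <- function(pt, poly) {
  n <- nrow(poly); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > pt[2]) != (poly[j, 2] > pt[2]) &&
        pt[1] < (poly[j, 1] - poly[i, 1]) * (pt[2] - poly[i, 2]) /
          (poly[j, 2] - poly[i, 2]) + poly[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

oracleNearestNeighbor <- function(xy) {
  n <- nrow(xy)
  vapply(seq_len(n), function(i) {
    best <- Inf
    for (j in seq_len(n)) if (j != i) {
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      if (d < best) best <- d
    }
    best
  }, numeric(1))
}

# flood-fill component labeling (8-connectivity 2-D, 26-connectivity 3-D)
oracleLabel <- function(mask) {
  d <- dim(mask); nd <- length(d)
  lab <- array(0L, dim = d)
  cur <- 0L
  idxAll <- which(mask)
  for (start in idxAll) {
    if (lab[start] > 0) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      if (nd == 2) {
        y <- (i - 1) %% d[1] + 1; x <- (i - 1) %/% d[1] + 1
        for (dy in -1:1) for (dx in -1:1) {
          yy <- y + dy; xx <- x + dx
          if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2]) next
          j <- yy + (xx - 1) * d[1]
          if (mask[j] && lab[j] == 0) { lab[j] <- cur; queue <- c(queue, j) }
        }
      } else {
        y <- (i - 1) %% d[1] + 1
        x <- ((i - 1) %/% d[1]) %% d[2] + 1
        z <- (i - 1) %/% (d[1] * d[2]) + 1
        for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
          yy <- y + dy; xx <- x + dx; zz <- z + dz
          if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] ||
              zz < 1 || zz > d[3]) next
          j <- yy + (xx - 1) * d[1] + (zz - 1) * d[1] * d[2]
          if (mask[j] && lab[j] == 0) { lab[j] <- cur; queue <- c(queue, j) }
        }
      }
    }
  }
  lab
}

# truth motility index of the generator projections for one layer
truthMotility <- function(truth, layer) {
  ms <- truth$mgProj[[layer]]
  mean(vapply(seq_len(length(ms) - 1), function(i)
    oracleMotility(ms[[i]], ms[[i + 1]]), numeric(1)))
}
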