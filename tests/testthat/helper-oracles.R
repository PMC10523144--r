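# Independent reference implementations used only by the tests.
#
# oracleRelRadiusInterp: scalar, loop-based polar-interpolation routine that
#   must agree with the package bit-for-bit.
# oracleRelRadiusIntersect: exact ray--edge intersection; agrees with the
#   package only in the many-vertex (circle) limit.

oracleBoundaryRadiusInterp <- function(poly, center, theta) {
  pol <- toPolar(vertices(poly), center)
  ord <- order(pol[, "theta"], pol[, "r"])
  phi <- pol[ord, "theta"]
  rho <- pol[ord, "r"]
  n <- length(phi)
  phiExt <- c(phi, phi[1] + 2 * pi)
  rhoExt <- c(rho, rho[1])
  t <- theta %% (2 * pi)
  if (t >= 2 * pi) t <- 0
  if (t < phi[1]) t <- t + 2 * pi
  i <- 0L
  for (k in seq_len(n + 1L)) if (phiExt[k] <= t) i <- k
  if (i > n) i <- n
  if (i < 1L) i <- 1L
  p1 <- phiExt[i]; p2 <- phiExt[i + 1L]
  r1 <- rhoExt[i]; r2 <- rhoExt[i + 1L]
  w <- if (p2 > p1) (t - p1) / (p2 - p1) else 0
  r1 + (r2 - r1) * w
}

oracleRelRadiusInterp <- function(point, poly, center = polygonCentroid(poly)) {
  dx <- point[1] - center[1]
  dy <- point[2] - center[2]
  r <- sqrt(dx * dx + dy * dy)
  theta <- atan2(dy, dx) %% (2 * pi)
  if (theta >= 2 * pi) theta <- 0
  if (r == 0) theta <- 0
  100 * r / oracleBoundaryRadiusInterp(poly, center, theta)
}

oracleRelRadiusIntersect <- function(point, poly,
                                     center = polygonCentroid(poly)) {
  dx <- point[1] - center[1]
  dy <- point[2] - center[2]
  r <- sqrt(dx * dx + dy * dy)
  theta <- if (r == 0) 0 else atan2(dy, dx)
  d <- c(cos(theta), sin(theta))
  v <- vertices(poly)
  n <- nrow(v)
  best <- Inf
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[if (i == n) 1L else i + 1L, ]
    e <- b - a
    denom <- d[1] * e[2] - d[2] * e[1]
    if (abs(denom) < 1e-14) next
    ac <- a - center
    u <- (ac[1] * e[2] - ac[2] * e[1]) / denom
    s <- (ac[1] * d[2] - ac[2] * d[1]) / denom
    if (u > 0 && s >= -1e-12 && s <= 1 + 1e-12) best <- min(best, u)
  }
  stopifnot(is.finite(best))
  100 * r / best
}

# random convex polygon as the hull of gaussian points, random size/offset
randomConvexPolygon <- function(nPts = 12, scale = NULL, offset = NULL) {
  repeat {
    pts <- matrix(stats::rnorm(2 * nPts), ncol = 2)
    hull <- grDevices::chull(pts)
    if (length(hull) >= 3) break
  }
  v <- pts[hull, , drop = FALSE]
  if (is.null(scale)) scale <- stats::runif(1, 0.5, 50)
  if (is.null(offset)) offset <- stats::rnorm(2, sd = 20)
  IsletPolygon(sweep(v * scale, 2, offset, "+"))
}

# random interior point of a convex polygon: Dirichlet-weighted vertex mix
randomInteriorPoint <- function(poly) {
  v <- vertices(poly)
  wts <- stats::rexp(nrow(v))
  wts <- wts / sum(wts)
  colSums(v * wts)
}

# positive-pixel centres of a mask, in (x, y) image coordinates
maskToPoints <- function(mask) {
  pos <- which(mask, arr.ind = TRUE)
  cbind(pos[, 2] - 0.5, pos[, 1] - 0.5)
}

regularNgon <- function(n, radius = 1, center = c(0, 0)) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  IsletPolygon(cbind(center[1] + radius * cos(phi),
                     center[2] + radius * sin(phi)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
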