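# Core geometry: polar transform of detected pixels about the polygon
# centre, angular linear interpolation of the boundary, relative radii and
# per-islet summaries.

#' @rdname IsletPolygon-class
#' @param object an \code{IsletPolygon}.
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))

#' @rdname IsletPolygon-class
#' @export
setMethod("vertices", "IsletPolygon", function(object) object@vertices)

#' @rdname IsletPolygon-class
#' @export
setGeneric("wasInvalid", function(object) standardGeneric("wasInvalid"))

#' @rdname IsletPolygon-class
#' @export
setMethod("wasInvalid", "IsletPolygon", function(object) object@wasInvalid)

#' Centre of an islet polygon
#'
#' Computes the polygon centre about which polar coordinates are taken. The
#' default is the arithmetic mean of the vertex coordinates, which is also
#' what the angular-monotonicity validity rule presupposes; the area-weighted
#' (shoelace) centroid is available as an alternative.
#'
#' The result is a deterministic function of the vertex set and invariant
#' under cyclic relabelling of the vertices. For convex polygons both
#' variants lie strictly inside the boundary.
#'
#' @param polygon an \code{\linkS4class{IsletPolygon}} or a two-column
#'   numeric matrix of vertices.
#' @param method \code{"vertex"} (mean of vertices, default) or \code{"area"}
#'   (area-weighted centroid).
#' @return numeric vector \code{c(x, y)}.
#' @examples
#' tri <- IsletPolygon(rbind(c(0, 0), c(3, 0), c(0, 3)))
#' polygonCentroid(tri)            # (1, 1)
#' polygonCentroid(tri, "area")    # (1, 1) for a triangle as well
#' @export
polygonCentroid <- function(polygon, method = c("vertex", "area")) {
  method <- match.arg(method)
  v <- if (is(polygon, "IsletPolygon")) polygon@vertices else {
    p <- IsletPolygon(polygon)  # reuse duplicate removal + degeneracy check
    p@vertices
  }
  if (method == "vertex") return(colMeans(v))
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps * max(1, sum(abs(v))))
    stop("degenerate polygon: zero signed area, area centroid undefined")
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

#' Cartesian to polar transform about the islet centre
#'
#' Transforms 2-D points to polar coordinates relative to a centre: the
#' radial component is the Euclidean distance to the centre and the angular
#' component is the angle with the positive horizontal axis, normalised to
#' \code{[0, 2*pi)}. Coordinates follow the image convention (y increases
#' downwards); the mathematics is unaffected. A point coinciding with the
#' centre has radius 0 and, by convention, angle 0.
#'
#' @param points a two-column numeric matrix (x, y) or a single \code{c(x, y)}.
#' @param center numeric \code{c(x, y)}.
#' @return a two-column matrix with columns \code{theta} (radians) and
#'   \code{r} (pixels), one row per input point.
#' @examples
#' toPolar(c(1, 0), c(0, 0))   # theta 0, r 1
#' toPolar(c(0, 1), c(0, 0))   # theta pi/2, r 1
#' @export
toPolar <- function(points, center) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 2)
  stopifnot(ncol(points) == 2, length(center) == 2, all(is.finite(center)))
  dx <- points[, 1] - center[1]
  dy <- points[, 2] - center[2]
  r <- sqrt(dx * dx + dy * dy)
  theta <- atan2(dy, dx) %% (2 * pi)
  theta[theta >= 2 * pi] <- 0  # guard against fp wrap of tiny negatives
  theta[r == 0] <- 0
  cbind(theta = theta, r = r)
}

#' Validate the angular ordering of an islet polygon
#'
#' The radial projection of a point onto the polygon sides is unambiguous
#' only if the vertex angles about the centre are weakly monotonic --
#' increasing or decreasing -- up to a single cyclic wraparound (a convex
#' polygon traversed from any start vertex has exactly one wrap, so convex
#' polygons are always valid; concave ones may or may not be). An invalid
#' polygon is repaired by sorting its vertices by ascending angle (ties by
#' ascending radius), which alters the drawn shape, so the repair is flagged
#' on the returned object (\code{\link{wasInvalid}}) and reported as a
#' warning.
#'
#' @param polygon an \code{\linkS4class{IsletPolygon}}.
#' @param center centre for the polar transform; defaults to the vertex-mean
#'   centroid.
#' @param tol angular tolerance in radians for the monotonicity test.
#' @return an \code{IsletPolygon}: the input unchanged if valid, otherwise
#'   the angle-sorted polygon with \code{wasInvalid = TRUE}.
#' @examples
#' sq <- IsletPolygon(rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)))
#' wasInvalid(validatePolygon(sq))   # FALSE: convex polygons are valid
#' @export
validatePolygon <- function(polygon, center = NULL, tol = 1e-9) {
  stopifnot(is(polygon, "IsletPolygon"))
  if (is.null(center)) center <- polygonCentroid(polygon)
  pol <- toPolar(polygon@vertices, center)
  phi <- pol[, "theta"]
  d <- diff(c(phi, phi[1]))             # n cyclic angle steps
  nDesc <- sum(d < -tol)
  nAsc <- sum(d > tol)
  if (nDesc <= 1L || nAsc <= 1L)        # weakly monotonic up to one wrap
    return(polygon)
  warning("invalid polygon: vertex angles about the centre are not weakly ",
          "monotonic; vertices were re-sorted by angle and the repair is ",
          "flagged", call. = FALSE)
  ord <- order(phi, pol[, "r"])
  new("IsletPolygon", vertices = polygon@vertices[ord, , drop = FALSE],
      wasInvalid = TRUE)
}

# Linear interpolation of vertex radius as a function of vertex angle, with
# circular wraparound (angle of first vertex + 2*pi). phi must be ascending;
# theta must be normalised to [0, 2*pi). Kept as a plain formula (no
# stats::approx) so a scalar reference loop reproduces it bit-for-bit.
.interpBoundary <- function(phi, rho, theta) {
  n <- length(phi)
  phiExt <- c(phi, phi[1] + 2 * pi)
  rhoExt <- c(rho, rho[1])
  t <- theta
  lo <- t < phi[1]
  t[lo] <- t[lo] + 2 * pi
  i <- findInterval(t, phiExt, rightmost.closed = TRUE)
  p1 <- phiExt[i]; p2 <- phiExt[i + 1L]
  r1 <- rhoExt[i]; r2 <- rhoExt[i + 1L]
  span <- p2 - p1
  w <- numeric(length(t))
  pos <- span > 0
  w[pos] <- (t[pos] - p1[pos]) / span[pos]
  r1 + (r2 - r1) * w
}

#' Boundary radius along a direction, by angular linear interpolation
#'
#' Returns the radius of the islet boundary at polar angle \code{theta},
#' obtained by linear interpolation of the vertex radii as a function of the
#' vertex angles, between the two vertices whose angles bracket \code{theta}
#' (with circular wraparound between the last and first vertex). This is the
#' projection of a direction onto the polygon sides used by
#' \code{\link{relativeRadii}}.
#'
#' Note that interpolating in (angle, radius) space is not the exact
#' ray--edge intersection: for a square queried between two vertices the
#' interpolated radius stays at the vertex radius (\code{sqrt(2)} for the
#' unit square) where the true edge intersection would be 1. The two agree
#' in the many-vertex limit; see the package vignette.
#'
#' @param polygon a validated \code{\linkS4class{IsletPolygon}}.
#' @param theta polar angle(s) in radians; values outside \code{[0, 2*pi)}
#'   are normalised, not rejected.
#' @param center centre of the polar transform; defaults to the vertex-mean
#'   centroid.
#' @return numeric vector of boundary radii, one per angle.
#' @examples
#' sq <- IsletPolygon(rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)))
#' boundaryRadius(sq, c(pi / 4, 0))   # sqrt(2), sqrt(2)
#' @export
boundaryRadius <- function(polygon, theta, center = NULL) {
  stopifnot(is(polygon, "IsletPolygon"))
  if (is.null(center)) center <- polygonCentroid(polygon)
  pol <- toPolar(polygon@vertices, center)
  ord <- order(pol[, "theta"], pol[, "r"])
  phi <- pol[ord, "theta"]
  rho <- pol[ord, "r"]
  if (any(rho <= 0))
    stop("polygon vertex coincides with the centre; boundary radius undefined")
  theta <- as.numeric(theta) %% (2 * pi)
  theta[theta >= 2 * pi] <- 0  # fp guard: (-eps) %% 2pi can round to 2pi
  .interpBoundary(phi, rho, theta)
}

# Even-odd (crossing number) point-in-polygon test, vectorised over points.
# Points whose distance to an edge is <= tol count as inside (boundary-
# grazing pixel centres belong to the islet).
.pointInPolygon <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  inside <- logical(length(px))
  onEdge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]
    xj <- vx[j]; yj <- vy[j]
    ex <- xj - xi; ey <- yj - yi
    len2 <- ex * ex + ey * ey
    if (len2 > 0) {
      tt <- ((px - xi) * ex + (py - yi) * ey) / len2
      tt <- pmin(1, pmax(0, tt))
      qx <- xi + tt * ex - px
      qy <- yi + tt * ey - py
      onEdge <- onEdge | (qx * qx + qy * qy <= tol * tol)
    }
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py - yi) * ex / ey
      flip <- crosses & (px < xint)
      flip[is.na(flip)] <- FALSE
      inside <- xor(inside, flip)
    }
    j <- i
  }
  inside | onEdge
}

#' Even-odd point-in-polygon test
#'
#' Tests whether points lie inside a polygon by the even-odd (crossing
#' number) rule. Points on the boundary (within \code{tol}) count as inside,
#' so a pixel centre grazing the drawn border still belongs to the islet.
#'
#' @param points two-column numeric matrix (x, y) or a single \code{c(x, y)}.
#' @param polygon an \code{\linkS4class{IsletPolygon}}.
#' @param tol boundary tolerance in pixels.
#' @return logical vector, one value per point.
#' @export
pointsInPolygon <- function(points, polygon, tol = 1e-9) {
  stopifnot(is(polygon, "IsletPolygon"))
  if (!is.matrix(points)) points <- matrix(points, ncol = 2)
  v <- polygon@vertices
  .pointInPolygon(points[, 1], points[, 2], v[, 1], v[, 2], tol = tol)
}

#' Relative radii of detected pixels within an islet polygon
#'
#' For each hormone-positive pixel, computes the ratio of the lengths of two
#' equidirectional segments starting at the islet centre: one bounded by the
#' pixel, one by the islet border (the latter via
#' \code{\link{boundaryRadius}}). The relative radius is
#' \code{100 * r / rBoundary} percent; the smaller it is, the closer the
#' cell lies to the islet centre. Points outside the polygon (detection runs
#' on the whole image) are discarded before any radius is computed and only
#' counted in the \code{nOutside} slot of the result; output order follows
#' input order for the retained points.
#'
#' @param polygon a validated \code{\linkS4class{IsletPolygon}}.
#' @param points two-column numeric matrix of detected pixel coordinates.
#' @param center centre of the polar transform; defaults to the vertex-mean
#'   centroid.
#' @return a \code{\linkS4class{PolarPointSet}}.
#' @examples
#' sq <- IsletPolygon(rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)))
#' pp <- relativeRadii(sq, rbind(c(0, 0), c(0.5, 0)))
#' as.data.frame(pp)$relRadius   # 0 and 100 * 0.5 / sqrt(2)
#' @export
relativeRadii <- function(polygon, points, center = NULL) {
  stopifnot(is(polygon, "IsletPolygon"))
  if (is.null(center)) center <- polygonCentroid(polygon)
  if (length(points) == 0) points <- matrix(numeric(0), ncol = 2)
  if (!is.matrix(points)) points <- matrix(points, ncol = 2)
  keep <- pointsInPolygon(points, polygon)
  nOutside <- sum(!keep)
  pts <- points[keep, , drop = FALSE]
  if (nrow(pts) == 0) {
    return(new("PolarPointSet", x = numeric(0), y = numeric(0),
               theta = numeric(0), r = numeric(0), rBoundary = numeric(0),
               relRadius = numeric(0), nOutside = as.integer(nOutside)))
  }
  pol <- toPolar(pts, center)
  rb <- boundaryRadius(polygon, pol[, "theta"], center = center)
  new("PolarPointSet",
      x = pts[, 1], y = pts[, 2],
      theta = pol[, "theta"], r = pol[, "r"], rBoundary = rb,
      relRadius = 100 * pol[, "r"] / rb,
      nOutside = as.integer(nOutside))
}

#' Relative hormone-positive area of an islet
#'
#' Counts the raster pixels belonging to the islet (pixel centres inside the
#' polygon by the even-odd rule; a pixel at 0-based integer position
#' \code{(x, y)} has its centre at \code{(x + 0.5, y + 0.5)}) and the
#' mask-positive pixels among them, and returns their ratio in percent.
#'
#' @param mask logical matrix of hormone-positivity, rows indexing y and
#'   columns indexing x (see \code{\link{detectCells}}).
#' @param polygon a validated \code{\linkS4class{IsletPolygon}} in the same
#'   pixel coordinate frame as \code{mask}.
#' @return a list with \code{nCellPixels}, \code{nIsletPixels},
#'   \code{relativeAreaPct}, and \code{inside}, a logical matrix the shape of
#'   \code{mask} marking the islet pixels.
#' @export
relativeArea <- function(mask, polygon) {
  stopifnot(is.logical(mask), is.matrix(mask), is(polygon, "IsletPolygon"))
  v <- polygon@vertices
  h <- nrow(mask); w <- ncol(mask)
  # restrict the inside test to the polygon's bounding box
  cols <- max(1L, floor(min(v[, 1]))):min(w, ceiling(max(v[, 1])) + 1L)
  rows <- max(1L, floor(min(v[, 2]))):min(h, ceiling(max(v[, 2])) + 1L)
  cx <- cols - 0.5
  cy <- rows - 0.5
  px <- rep(cx, each = length(cy))
  py <- rep(cy, times = length(cx))
  ins <- .pointInPolygon(px, py, v[, 1], v[, 2])
  inside <- matrix(FALSE, h, w)
  inside[rows, cols] <- matrix(ins, nrow = length(rows), ncol = length(cols))
  nIslet <- sum(inside)
  if (nIslet == 0L)
    stop("degenerate polygon: no raster pixel centre lies inside it")
  nCell <- sum(mask & inside)
  list(nCellPixels = nCell, nIsletPixels = nIslet,
       relativeAreaPct = 100 * nCell / nIslet, inside = inside)
}

#' Per-islet summary of the relative-radius analysis
#'
#' Averages the relative radii of one islet. Because an invalid polygon is
#' repaired by angle sorting, radii greater than 100\% can occur; these are
#' excluded from averaging (radii of exactly 100\% are kept) and the
#' percentage of excluded radii is reported alongside the mean. An islet
#' with no included radii -- in particular one with no staining at all -- is
#' flagged excluded and its mean reported as missing, never as 0.
#'
#' @param points a \code{\linkS4class{PolarPointSet}} from
#'   \code{\link{relativeRadii}}.
#' @param area result of \code{\link{relativeArea}} for the same islet, or
#'   \code{NULL} if no mask was analysed.
#' @param imageId,isletId identifiers copied into the result row.
#' @param stainMode \code{"ihc"} or \code{"if"}, copied into the result row.
#' @param polygonWasInvalid logical, whether the polygon was auto-sorted.
#' @return a one-row \code{data.frame} with columns \code{image_id},
#'   \code{islet_id}, \code{stain_mode}, \code{n_cell_pixels},
#'   \code{n_islet_pixels}, \code{relative_area_pct},
#'   \code{mean_relative_radius_pct}, \code{n_included}, \code{n_excluded},
#'   \code{pct_excluded}, \code{polygon_was_invalid},
#'   \code{excluded_no_staining}.
#' @examples
#' pp <- new("PolarPointSet", x = 1:4, y = rep(0, 4),
#'           theta = rep(0, 4), r = c(2, 4, 6, 12),
#'           rBoundary = rep(10, 4), relRadius = c(20, 40, 60, 120),
#'           nOutside = 0L)
#' isletSummary(pp)[, c("mean_relative_radius_pct", "pct_excluded")]
#' @export
isletSummary <- function(points, area = NULL, imageId = NA_character_,
                         isletId = NA_character_, stainMode = NA_character_,
                         polygonWasInvalid = FALSE) {
  stopifnot(is(points, "PolarPointSet"))
  rel <- points@relRadius
  included <- rel <= 100
  nInc <- sum(included)
  nExc <- sum(!included)
  total <- nInc + nExc
  data.frame(
    image_id = as.character(imageId),
    islet_id = as.character(isletId),
    stain_mode = as.character(stainMode),
    n_cell_pixels = total,
    n_islet_pixels = if (is.null(area)) NA_integer_ else area$nIsletPixels,
    relative_area_pct = if (is.null(area)) NA_real_ else area$relativeAreaPct,
    mean_relative_radius_pct = if (nInc > 0) mean(rel[included]) else NA_real_,
    n_included = nInc,
    n_excluded = nExc,
    pct_excluded = if (total > 0) 100 * nExc / total else NA_real_,
    polygon_was_invalid = isTRUE(polygonWasInvalid),
    excluded_no_staining = nInc == 0L,
    stringsAsFactors = FALSE
  )
}
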