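#' @import methods
NULL

setClassUnion("numericOrCharacter", c("numeric", "character"))

#' Islet boundary polygon
#'
#' An ordered list of 2-D vertices delimiting one islet of Langerhans in
#' image pixel coordinates (x rightwards, y downwards, continuous values
#' permitted). Consecutive duplicate vertices (including a repeated closing
#' vertex) are removed on construction. The \code{wasInvalid} slot records
#' whether angular auto-sorting was applied by \code{\link{validatePolygon}}.
#'
#' @slot vertices numeric matrix with two columns (x, y), one row per vertex.
#' @slot wasInvalid logical, \code{TRUE} if the vertex order had to be
#'   repaired by sorting on the polar angle about the centroid.
#'
#' @seealso \code{\link{IsletPolygon}}, \code{\link{validatePolygon}},
#'   \code{\link{polygonCentroid}}
#' @name IsletPolygon-class
#' @exportClass IsletPolygon
setClass("IsletPolygon",
  representation(vertices = "matrix", wasInvalid = "logical"),
  prototype(vertices = matrix(numeric(0), ncol = 2), wasInvalid = FALSE),
  validity = function(object) {
    v <- object@vertices
    if (!is.numeric(v) || ncol(v) != 2L)
      return("'vertices' must be a numeric matrix with two columns (x, y)")
    if (nrow(v) < 3L)
      return("a polygon needs at least 3 vertices")
    if (!all(is.finite(v)))
      return("vertex coordinates must be finite")
    if (length(object@wasInvalid) != 1L)
      return("'wasInvalid' must be a single logical")
    TRUE
  }
)

#' Construct an IsletPolygon
#'
#' Builds an \code{\linkS4class{IsletPolygon}} from a two-column matrix (or a
#' list of \code{c(x, y)} pairs), dropping consecutive duplicate vertices and
#' a duplicated closing vertex. At least 3 distinct vertices must remain.
#'
#' @param vertices two-column numeric matrix (x, y) or a list of length-2
#'   numeric vectors.
#' @param wasInvalid logical flag, normally left \code{FALSE}; set by
#'   \code{\link{validatePolygon}} when auto-sorting was applied.
#' @return an \code{IsletPolygon} object.
#' @examples
#' sq <- IsletPolygon(rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)))
#' polygonCentroid(sq)
#' @export
IsletPolygon <- function(vertices, wasInvalid = FALSE) {
  if (is.list(vertices))
    vertices <- do.call(rbind, lapply(vertices, as.numeric))
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2L)
    stop("'vertices' must have two columns (x, y)")
  if (!all(is.finite(vertices)))
    stop("vertex coordinates must be finite")
  # drop consecutive duplicates, cyclically (handles an explicit closing vertex)
  n <- nrow(vertices)
  if (n > 1L) {
    nxt <- c(2:n, 1L)
    dup <- rowSums(abs(vertices - vertices[nxt, , drop = FALSE])) == 0
    # dup[i] TRUE means vertex i equals its successor; keep the successor
    vertices <- vertices[!dup, , drop = FALSE]
  }
  if (nrow(vertices) < 3L || nrow(unique(vertices)) < 3L)
    stop("degenerate polygon: fewer than 3 distinct vertices")
  new("IsletPolygon", vertices = vertices, wasInvalid = wasInvalid)
}

#' @describeIn IsletPolygon-class number of vertices.
#' @param x an \code{IsletPolygon}.
#' @export
setMethod("length", "IsletPolygon", function(x) nrow(x@vertices))

setMethod("show", "IsletPolygon", function(object) {
  cat(sprintf("IsletPolygon with %d vertices%s\n", nrow(object@vertices),
              if (object@wasInvalid) " (auto-sorted from invalid input)" else ""))
  ctr <- polygonCentroid(object)
  cat(sprintf("  centroid (vertex mean): (%.3f, %.3f)\n", ctr[1], ctr[2]))
})

#' Detected pixels in polar coordinates about the islet centre
#'
#' Stores, for each hormone-positive pixel retained for analysis, its polar
#' angle, its distance to the polygon centre, the interpolated boundary
#' radius along the same direction (the projection onto the polygon sides),
#' and the resulting relative radius in percent. Pixels detected outside the
#' polygon are discarded before construction and only counted in
#' \code{nOutside}.
#'
#' @slot x,y original pixel coordinates of the retained points.
#' @slot theta polar angle in radians, in \code{[0, 2*pi)}, measured from the
#'   positive horizontal axis; a zero-radius point gets angle 0 by convention.
#' @slot r Euclidean distance to the polygon centre, in pixels.
#' @slot rBoundary interpolated boundary radius at \code{theta}, in pixels.
#' @slot relRadius relative radius in percent, \code{100 * r / rBoundary}.
#' @slot nOutside number of detected pixels discarded for lying outside the
#'   polygon (not part of the exclusion-percentage accounting).
#'
#' @seealso \code{\link{relativeRadii}}, \code{\link{isletSummary}}
#' @name PolarPointSet-class
#' @exportClass PolarPointSet
setClass("PolarPointSet",
  representation(x = "numeric", y = "numeric", theta = "numeric",
                 r = "numeric", rBoundary = "numeric", relRadius = "numeric",
                 nOutside = "integer"),
  prototype(nOutside = 0L),
  validity = function(object) {
    n <- length(object@theta)
    if (length(object@r) != n || length(object@rBoundary) != n ||
        length(object@relRadius) != n || length(object@x) != n ||
        length(object@y) != n)
      return("all coordinate slots must have equal length")
    if (n > 0) {
      if (any(object@r < 0)) return("radial distances must be non-negative")
      if (any(object@theta < 0 | object@theta >= 2 * pi))
        return("angles must lie in [0, 2*pi)")
      if (any(object@rBoundary <= 0))
        return("boundary radii must be strictly positive")
    }
    if (length(object@nOutside) != 1L || is.na(object@nOutside) ||
        object@nOutside < 0L)
      return("'nOutside' must be a single non-negative integer")
    TRUE
  }
)

#' @describeIn PolarPointSet-class number of retained points.
#' @param x a \code{PolarPointSet}.
#' @export
setMethod("length", "PolarPointSet", function(x) length(x@theta))

#' @describeIn PolarPointSet-class coerce to a data.frame with columns
#'   \code{x}, \code{y}, \code{theta}, \code{r}, \code{rBoundary},
#'   \code{relRadius}.
#' @param row.names,optional,... passed on conventions of
#'   \code{\link[base]{as.data.frame}}; ignored.
#' @export
setMethod("as.data.frame", "PolarPointSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(x = x@x, y = x@y, theta = x@theta, r = x@r,
               rBoundary = x@rBoundary, relRadius = x@relRadius)
  })

setMethod("show", "PolarPointSet", function(object) {
  cat(sprintf("PolarPointSet with %d points (%d discarded outside polygon)\n",
              length(object@theta), object@nOutside))
  if (length(object@theta) > 0)
    cat(sprintf("  relative radius: %.2f%% .. %.2f%% (median %.2f%%)\n",
                min(object@relRadius), max(object@relRadius),
                stats::median(object@relRadius)))
})

#' Detection thresholds for hormone-positive pixels
#'
#' Configuration of the thresholding step. In \code{ihc} mode an RGB image is
#' converted to HSV and a pixel is positive iff its (hue, saturation, value)
#' triple lies in the configured box; the hue interval may wrap around 0/360.
#' In \code{if} mode a grayscale image is thresholded on intensity, either at
#' a fixed level or per image by Otsu's criterion.
#'
#' @slot mode \code{"ihc"} (colour, DAB chromogen) or \code{"if"}
#'   (immunofluorescence grayscale).
#' @slot hsvLower,hsvUpper numeric length-3 vectors: hue in degrees
#'   \code{[0, 360)}, saturation and value in \code{[0, 1]}. A lower hue
#'   greater than the upper hue denotes the wrapped interval.
#' @slot ifThreshold intensity level in \code{[0, 1]}, or the string
#'   \code{"otsu"} for a per-image automatic threshold.
#' @slot minBlobSize minimum connected-component size in pixels kept in the
#'   mask; 0 (default) disables the filter.
#'
#' @seealso \code{\link{DetectionConfig}}, \code{\link{detectCells}}
#' @name DetectionConfig-class
#' @exportClass DetectionConfig
setClass("DetectionConfig",
  representation(mode = "character", hsvLower = "numeric",
                 hsvUpper = "numeric", ifThreshold = "numericOrCharacter",
                 minBlobSize = "numeric"),
  validity = function(object) {
    if (!object@mode %in% c("ihc", "if"))
      return("'mode' must be \"ihc\" or \"if\"")
    for (v in list(object@hsvLower, object@hsvUpper)) {
      if (length(v) != 3L || any(!is.finite(v)))
        return("'hsvLower'/'hsvUpper' must be finite numeric length-3 (h, s, v)")
    }
    if (object@hsvLower[1] < 0 || object@hsvLower[1] >= 360 ||
        object@hsvUpper[1] < 0 || object@hsvUpper[1] >= 360)
      return("hue bounds must lie in [0, 360)")
    if (any(object@hsvLower[2:3] < 0) || any(object@hsvUpper[2:3] > 1) ||
        any(object@hsvLower[2:3] > object@hsvUpper[2:3]))
      return("saturation/value bounds must satisfy 0 <= lower <= upper <= 1")
    th <- object@ifThreshold
    if (is.character(th)) {
      if (!identical(th, "otsu"))
        return("character 'ifThreshold' must be \"otsu\"")
    } else if (length(th) != 1L || !is.finite(th) || th < 0 || th > 1) {
      return("numeric 'ifThreshold' must be a single value in [0, 1]")
    }
    if (length(object@minBlobSize) != 1L || object@minBlobSize < 0)
      return("'minBlobSize' must be a single non-negative number")
    TRUE
  }
)

#' Construct a DetectionConfig
#'
#' Defaults are documented heuristics, not values from any particular stain
#' batch: the IHC box targets the earthy red-brown of a DAB chromogen
#' (hue 0--50 degrees, saturation at least 0.2, value 0.1--0.95) and should be
#' tuned to the staining at hand; the IF default is Otsu's automatic
#' threshold.
#'
#' @param mode \code{"ihc"} or \code{"if"}.
#' @param hsvLower,hsvUpper HSV box bounds; hue in degrees \code{[0, 360)},
#'   saturation/value in \code{[0, 1]}. \code{hsvLower[1] > hsvUpper[1]}
#'   denotes a hue interval wrapping through 0.
#' @param ifThreshold intensity threshold in \code{[0, 1]} or \code{"otsu"}.
#' @param minBlobSize minimum connected-component size kept (pixels);
#'   0 disables the filter.
#' @return a \code{DetectionConfig} object.
#' @examples
#' DetectionConfig("ihc")
#' DetectionConfig("if", ifThreshold = 0.4)
#' @export
DetectionConfig <- function(mode = c("ihc", "if"),
                            hsvLower = c(0, 0.2, 0.1),
                            hsvUpper = c(50, 1, 0.95),
                            ifThreshold = "otsu",
                            minBlobSize = 0) {
  mode <- match.arg(mode)
  new("DetectionConfig", mode = mode,
      hsvLower = as.numeric(hsvLower), hsvUpper = as.numeric(hsvUpper),
      ifThreshold = if (is.character(ifThreshold)) ifThreshold
                    else as.numeric(ifThreshold),
      minBlobSize = as.numeric(minBlobSize))
}

setMethod("show", "DetectionConfig", function(object) {
  cat(sprintf("DetectionConfig, mode '%s'\n", object@mode))
  if (object@mode == "ihc") {
    cat(sprintf("  HSV box: hue %g..%g deg%s, sat %g..%g, val %g..%g\n",
                object@hsvLower[1], object@hsvUpper[1],
                if (object@hsvLower[1] > object@hsvUpper[1]) " (wrapped)" else "",
                object@hsvLower[2], object@hsvUpper[2],
                object@hsvLower[3], object@hsvUpper[3]))
  } else {
    cat(sprintf("  intensity threshold: %s\n",
                if (is.character(object@ifThreshold)) "otsu (per image)"
                else format(object@ifThreshold)))
  }
  if (object@minBlobSize > 0)
    cat(sprintf("  minimum blob size: %g px\n", object@minBlobSize))
})
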