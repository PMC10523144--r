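# Hormone-positive pixel detection: HSV box thresholding for DAB-stained
# colour images, intensity thresholding (fixed or Otsu) for fluorescence.

.hsvOfImage <- function(image) {
  # image: h x w x 3 array in [0, 1] -> 3 x (h*w) HSV matrix, hue in [0, 1]
  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1]),
               as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  grDevices::rgb2hsv(rgb, maxColorValue = 1)
}

.applyBlobFilter <- function(mask, minBlobSize) {
  if (minBlobSize <= 0 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  labm <- t(EBImage::imageData(lab))
  sizes <- tabulate(labm[labm > 0])
  keep <- which(sizes >= minBlobSize)
  mask & matrix(labm %in% keep, nrow(mask), ncol(mask))
}

#' Threshold a DAB-stained colour image in HSV space
#'
#' Converts an RGB image to HSV and marks a pixel hormone-positive iff its
#' (hue, saturation, value) triple lies inside the configured box. The hue
#' interval may wrap through 0/360 degrees (configured as lower > upper),
#' which matters for the earthy red-brown of the DAB chromogen sitting near
#' hue 0.
#'
#' @param image numeric array \code{h x w x 3} with values in \code{[0, 1]}
#'   (rows index y, columns x), as returned by \code{\link{readRasterImage}}.
#' @param config a \code{\linkS4class{DetectionConfig}} with
#'   \code{mode = "ihc"}.
#' @return logical \code{h x w} matrix; attribute \code{nPositive} holds the
#'   positive-pixel count.
#' @seealso \code{\link{detectCells}}, \code{\link{thresholdIF}}
#' @export
thresholdIHC <- function(image, config) {
  stopifnot(is(config, "DetectionConfig"))
  if (config@mode != "ihc")
    stop("mode mismatch: thresholdIHC needs a config with mode \"ihc\"")
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("mode mismatch: ihc detection needs a 3-channel RGB image")
  hsv <- .hsvOfImage(image)
  hue <- hsv[1, ] * 360
  lo <- config@hsvLower; hi <- config@hsvUpper
  hueOk <- if (lo[1] <= hi[1]) hue >= lo[1] & hue <= hi[1]
           else hue >= lo[1] | hue <= hi[1]   # wrapped interval
  pos <- hueOk &
    hsv[2, ] >= lo[2] & hsv[2, ] <= hi[2] &
    hsv[3, ] >= lo[3] & hsv[3, ] <= hi[3]
  mask <- matrix(pos, nrow = dim(image)[1], ncol = dim(image)[2])
  mask <- .applyBlobFilter(mask, config@minBlobSize)
  attr(mask, "nPositive") <- sum(mask)
  mask
}

#' Threshold a fluorescence grayscale image on intensity
#'
#' Marks a pixel hormone-positive iff its intensity is at least the
#' threshold. With \code{ifThreshold = "otsu"} the threshold is computed per
#' image by Otsu's criterion (via \code{\link[EBImage]{otsu}}); a constant
#' image has no Otsu threshold and yields an all-negative mask with a
#' warning.
#'
#' @param image numeric \code{h x w} matrix with values in \code{[0, 1]}.
#' @param config a \code{\linkS4class{DetectionConfig}} with
#'   \code{mode = "if"}.
#' @return logical \code{h x w} matrix; attribute \code{nPositive} holds the
#'   positive-pixel count, attribute \code{threshold} the level used.
#' @export
thresholdIF <- function(image, config) {
  stopifnot(is(config, "DetectionConfig"))
  if (config@mode != "if")
    stop("mode mismatch: thresholdIF needs a config with mode \"if\"")
  if (length(dim(image)) == 3L) {
    if (dim(image)[3] == 1L) image <- image[, , 1]
    else stop("mode mismatch: if detection needs a single-channel image")
  }
  stopifnot(is.matrix(image))
  th <- config@ifThreshold
  if (is.character(th)) {
    rng <- range(image)
    if (rng[1] == rng[2]) {
      warning("constant image: Otsu threshold undefined, returning an ",
              "all-negative mask", call. = FALSE)
      mask <- matrix(FALSE, nrow(image), ncol(image))
      attr(mask, "nPositive") <- 0L
      attr(mask, "threshold") <- NA_real_
      return(mask)
    }
    th <- EBImage::otsu(EBImage::Image(t(image)), range = c(0, 1))
  }
  mask <- image >= th
  mask <- .applyBlobFilter(mask, config@minBlobSize)
  attr(mask, "nPositive") <- sum(mask)
  attr(mask, "threshold") <- as.numeric(th)
  mask
}

#' Detect hormone-positive pixels
#'
#' Dispatches on \code{config@mode} to \code{\link{thresholdIHC}} (colour,
#' immunohistochemistry) or \code{\link{thresholdIF}} (grayscale,
#' immunofluorescence). Detection is deterministic and idempotent: the same
#' image and config always give the same mask.
#'
#' @param image image array from \code{\link{readRasterImage}}.
#' @param config a \code{\linkS4class{DetectionConfig}}.
#' @return logical mask matrix, same height/width as the image.
#' @export
detectCells <- function(image, config) {
  stopifnot(is(config, "DetectionConfig"))
  if (config@mode == "ihc") thresholdIHC(image, config)
  else thresholdIF(image, config)
}
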