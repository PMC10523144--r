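# Image loading and display-only helpers. Internally images are plain
# numeric arrays in [0, 1], rows indexing y (top to bottom) and columns x,
# i.e. the transpose of EBImage's width-first layout.

#' Read a raster image for analysis
#'
#' Loads a TIFF/JPG/PNG image via \code{\link[EBImage]{readImage}} and
#' returns it as a numeric array with rows indexing y and columns indexing
#' x, values in \code{[0, 1]}: an \code{h x w} matrix for grayscale input or
#' an \code{h x w x 3} array for colour. Of a multi-frame (multi-page TIFF)
#' file only the first frame is used, with a warning. An alpha channel, if
#' present, is dropped.
#'
#' @param path image file path.
#' @return numeric matrix or 3-d array.
#' @export
readRasterImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  isColor <- EBImage::colorMode(img) == EBImage::Color
  nFrames <- EBImage::numberOfFrames(img, type = "render")
  if (nFrames > 1L) {
    warning("multi-frame image '", basename(path),
            "': only the first frame is analysed", call. = FALSE)
    img <- EBImage::getFrame(img, 1L, type = "render")
    d <- dim(img)
  }
  a <- EBImage::imageData(img)
  if (isColor && length(dim(a)) == 3L) {
    if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(a)[3] == 1L) return(t(a[, , 1]))
    aperm(a, c(2, 1, 3))
  } else {
    if (length(dim(a)) == 3L) a <- a[, , 1]
    t(a)
  }
}

#' Write an analysis-frame image to disk
#'
#' Counterpart of \code{\link{readRasterImage}} used by the synthetic-islet
#' generator: takes an \code{h x w} matrix or \code{h x w x 3} array in
#' \code{[0, 1]} and writes it via \code{\link[EBImage]{writeImage}}.
#'
#' @param image numeric matrix or 3-d array, values in \code{[0, 1]}.
#' @param path destination file; format follows the extension.
#' @return the path, invisibly.
#' @export
writeRasterImage <- function(image, path) {
  img <- if (length(dim(image)) == 3L)
    EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  else
    EBImage::Image(t(image), colormode = "Grayscale")
  EBImage::writeImage(img, path)
  invisible(path)
}

#' Contrast-stretch a support image for display
#'
#' Support images (typically DAPI nuclear stains placed in a
#' \code{support/} subfolder) assist the user in drawing the islet border.
#' For convenience their contrast is increased by a min--max percentile
#' stretch -- but strictly for display: the analysis never consumes the
#' stretched pixels, and results are identical whether or not a support
#' image is present.
#'
#' @param image numeric grayscale matrix in \code{[0, 1]}.
#' @param probs two quantile probabilities mapped to 0 and 1; the default
#'   \code{c(0, 1)} is a pure min--max stretch.
#' @return stretched copy of \code{image}, clipped to \code{[0, 1]};
#'   a constant image is returned unchanged.
#' @export
enhanceSupportForDisplay <- function(image, probs = c(0, 1)) {
  stopifnot(is.numeric(image), length(probs) == 2)
  q <- stats::quantile(image, probs = probs, names = FALSE)
  if (q[2] <= q[1]) return(image)
  out <- (image - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
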