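# Synthetic stained-islet generator with exact ground truth. Emulates the
# two staining modes (DAB brown blobs on a counterstain-like background;
# bright fluorescence blobs on a dark background) so the whole pipeline is
# testable without microscope data.

.hexToRgb01 <- function(hex) as.numeric(grDevices::col2rgb(hex)) / 255

# defaults chosen relative to the default detection box: foreground sampled
# well inside it, background well outside (heuristic counterstain tones)
.ihcForeground <- function() .hexToRgb01(grDevices::hsv(30 / 360, 0.6, 0.55))
.ihcBackground <- function() .hexToRgb01(grDevices::hsv(270 / 360, 0.25, 0.85))

#' Generate one synthetic stained islet with ground truth
#'
#' Renders round cell "blobs" at prescribed relative radial positions inside
#' a polygonal islet boundary, in either staining mode, and returns the
#' image, the boundary polygon, and exact per-pixel ground truth. Blob
#' centres are placed at \code{center + fraction * boundaryRadius(theta) *
#' (cos(theta), sin(theta))}, i.e. the generator uses the same angular
#' interpolation of the boundary as the analysis, so for circle-like
#' polygons the pipeline should recover the intended fractions closely.
#'
#' @param fractions numeric vector of intended relative radii (0..1), one
#'   per blob.
#' @param angles blob direction angles in radians, recycled; \code{NULL}
#'   draws them uniformly on \code{[0, 2*pi)}.
#' @param blobRadius blob radius in pixels; values below 0.5 give
#'   single-pixel blobs.
#' @param mode \code{"ihc"} (RGB, DAB-brown blobs) or \code{"if"}
#'   (grayscale, bright blobs).
#' @param imageSize \code{c(height, width)} in pixels.
#' @param nVertices number of boundary polygon vertices (regular n-gon).
#' @param boundaryRadiusPx circumradius of the boundary polygon in pixels.
#' @param center polygon centre \code{c(x, y)}; default is the image centre.
#' @param jitterSd multiplicative vertex-radius jitter (standard deviation,
#'   relative); 0 gives a regular n-gon.
#' @param noiseSd additive Gaussian pixel noise (intensity units), clipped
#'   to \code{[0, 1]}; default 0.
#' @param foreground,background blob / background colour (length-3 RGB in
#'   \code{[0, 1]}) for \code{ihc}, or intensities in \code{[0, 1]} for
#'   \code{if}.
#' @param seed optional integer seed; the seed fully determines the output.
#' @return list with \code{image} (array as in
#'   \code{\link{readRasterImage}}), \code{polygon}
#'   (\code{\linkS4class{IsletPolygon}}), and \code{truth}: a list with the
#'   per-pixel positivity \code{map}, \code{nPositive}, per-blob
#'   \code{blobs} (centre, angle, fraction, pixel count) and
#'   \code{meanFractionPct}, the pixel-weighted intended mean relative
#'   radius in percent.
#' @examples
#' isl <- simulateIslet(fractions = rep(0.5, 10), mode = "if", seed = 1)
#' isl$truth$meanFractionPct
#' @export
simulateIslet <- function(fractions, angles = NULL, blobRadius = 1.5,
                          mode = c("ihc", "if"), imageSize = c(256, 256),
                          nVertices = 128, boundaryRadiusPx = 80,
                          center = NULL, jitterSd = 0, noiseSd = 0,
                          foreground = NULL, background = NULL,
                          seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  h <- imageSize[1]; w <- imageSize[2]
  if (is.null(center)) center <- c(w / 2, h / 2)
  stopifnot(all(fractions >= 0), all(fractions <= 1))

  phi <- 2 * pi * (seq_len(nVertices) - 1) / nVertices
  rad <- boundaryRadiusPx * (1 + if (jitterSd > 0)
    stats::rnorm(nVertices, sd = jitterSd) else 0)
  rad <- pmax(rad, boundaryRadiusPx * 0.2)
  poly <- IsletPolygon(cbind(center[1] + rad * cos(phi),
                             center[2] + rad * sin(phi)))
  ctr <- polygonCentroid(poly)

  nBlobs <- length(fractions)
  ang <- if (is.null(angles)) stats::runif(nBlobs, 0, 2 * pi)
         else rep_len(angles, nBlobs)
  rb <- boundaryRadius(poly, ang, center = ctr)
  bx <- ctr[1] + fractions * rb * cos(ang)
  by <- ctr[2] + fractions * rb * sin(ang)
  if (any(bx < 0 | bx > w | by < 0 | by > h))
    stop("blob placed outside image bounds; enlarge the image or shrink ",
         "the boundary")

  map <- matrix(FALSE, h, w)
  blobPix <- integer(nBlobs)
  for (b in seq_len(nBlobs)) {
    if (blobRadius < 0.5) {
      rr <- floor(by[b]) + 1L; cc <- floor(bx[b]) + 1L
      sel <- cbind(rr, cc)
    } else {
      cs <- max(1L, floor(bx[b] - blobRadius)):min(w, ceiling(bx[b] + blobRadius) + 1L)
      rs <- max(1L, floor(by[b] - blobRadius)):min(h, ceiling(by[b] + blobRadius) + 1L)
      px <- rep(cs - 0.5, each = length(rs))
      py <- rep(rs - 0.5, times = length(cs))
      hit <- (px - bx[b])^2 + (py - by[b])^2 <= blobRadius^2
      sel <- cbind(rep(rs, times = length(cs))[hit],
                   rep(cs, each = length(rs))[hit])
    }
    blobPix[b] <- nrow(sel)
    map[sel] <- TRUE
  }

  if (mode == "ihc") {
    fg <- foreground %||% .ihcForeground()
    bg <- background %||% .ihcBackground()
    image <- array(rep(bg, each = h * w), dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- image[, , ch]
      plane[map] <- fg[ch]
      image[, , ch] <- plane
    }
  } else {
    fg <- foreground %||% 0.9
    bg <- background %||% 0.1
    image <- matrix(bg, h, w)
    image[map] <- fg
  }
  if (noiseSd > 0) {
    image <- image + stats::rnorm(length(image), sd = noiseSd)
    image[image < 0] <- 0
    image[image > 1] <- 1
  }

  blobs <- data.frame(x = bx, y = by, angle = ang, fraction = fractions,
                      nPixels = blobPix)
  list(image = image, polygon = poly,
       truth = list(map = map, nPositive = sum(map), blobs = blobs,
                    meanFractionPct =
                      100 * sum(fractions * blobPix) / sum(blobPix)))
}

.drawFractions <- function(phenotype, n) {
  switch(phenotype,
    mantle = stats::runif(n, 0.85, 0.95),
    core = stats::runif(n, 0.2, 0.4),
    diffuse = sqrt(stats::runif(n)),  # area-uniform on a disc: E[f] = 2/3
    stop("unknown phenotype: ", phenotype))
}

#' Generate a cohort of synthetic islet images with a truth table
#'
#' Writes \code{n} synthetic islet images, their polygon sidecars and a
#' \code{truth.csv} into a folder, emulating three localisation phenotypes:
#' \code{mantle} (cells at the islet periphery, fractions uniform on
#' 0.85--0.95, the rodent mantle-core arrangement of alpha/delta cells),
#' \code{core} (fractions uniform on 0.2--0.4), and \code{diffuse}
#' (area-uniform over the islet disc, expected relative radius 2/3). For
#' \code{mode = "if"} a \code{support/} subfolder with DAPI-like nuclear
#' images (prefix-matched, display-only) is also written.
#'
#' @param n number of islets (one image each).
#' @param phenotype \code{"mantle"}, \code{"core"} or \code{"diffuse"}.
#' @param mode staining mode, \code{"ihc"} or \code{"if"}.
#' @param dir output folder, created if needed.
#' @param seed integer seed; fully determines the cohort.
#' @param nBlobs cell blobs per islet.
#' @param blobRadius blob radius in pixels.
#' @param nVertices boundary polygon vertices per islet.
#' @param imageSize image \code{c(height, width)}.
#' @param writeSupport write the support subfolder; defaults to
#'   \code{mode == "if"}.
#' @return invisibly, the truth table: one row per islet with columns
#'   \code{image}, \code{islet_id}, \code{n_blobs}, \code{n_positive},
#'   \code{intended_mean_fraction_pct}; also written to
#'   \code{<dir>/truth.csv}.
#' @export
simulateCohort <- function(n, phenotype = c("mantle", "core", "diffuse"),
                           mode = c("ihc", "if"), dir, seed = 1,
                           nBlobs = 40, blobRadius = 1.5, nVertices = 128,
                           imageSize = c(256, 256),
                           writeSupport = (mode == "if")) {
  phenotype <- match.arg(phenotype)
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    radius <- stats::runif(1, 55, 90)
    ctr <- imageSize[c(2, 1)] / 2 + stats::runif(2, -10, 10)
    fr <- .drawFractions(phenotype, nBlobs)
    isl <- simulateIslet(fractions = fr, blobRadius = blobRadius,
                         mode = mode, imageSize = imageSize,
                         nVertices = nVertices, boundaryRadiusPx = radius,
                         center = ctr)
    img <- sprintf("islet_%03d.png", i)
    writeRasterImage(isl$image, file.path(dir, img))
    writePolygonFile(img, list(list(id = "1", polygon = isl$polygon)),
                     file.path(dir, paste0("islet_", sprintf("%03d", i),
                                           ".polygons.json")))
    if (isTRUE(writeSupport)) {
      supDir <- file.path(dir, "support")
      dir.create(supDir, showWarnings = FALSE)
      nuclei <- matrix(0.05, imageSize[1], imageSize[2])
      nn <- 200
      nx <- floor(stats::runif(nn, 0, imageSize[2])) + 1L
      ny <- floor(stats::runif(nn, 0, imageSize[1])) + 1L
      nuclei[cbind(ny, nx)] <- 0.5
      writeRasterImage(nuclei,
                       file.path(supDir, sprintf("islet_%03d_dapi.png", i)))
    }
    rows[[i]] <- data.frame(image = img, islet_id = "1",
                            n_blobs = nBlobs,
                            n_positive = isl$truth$nPositive,
                            intended_mean_fraction_pct =
                              isl$truth$meanFractionPct,
                            stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}
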