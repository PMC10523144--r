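# Batch pipeline: image discovery, polygon sidecar files, support-image
# matching, per-islet analysis, CSV/XLSX export.

.imageExtensions <- c("tif", "tiff", "jpg", "jpeg", "png")

.stripExtension <- function(path) tools::file_path_sans_ext(path)

#' Read an islet-polygon sidecar file
#'
#' Polygon sidecars are JSON files of the form
#' \code{{"image": "<filename>", "islets": [{"id": ..., "vertices":
#' [[x, y], ...]}, ...]}}, one per image, named after the image with a
#' \code{.polygons.json} suffix (e.g. \code{A01.tif} has
#' \code{A01.polygons.json}).
#'
#' @param path path to the \code{.polygons.json} file.
#' @return list with \code{image} (character) and \code{islets}, a list of
#'   \code{list(id = ..., polygon = IsletPolygon)}.
#' @seealso \code{\link{writePolygonFile}}
#' @export
readPolygonFile <- function(path) {
  if (!file.exists(path)) stop("polygon file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$islets)) stop("polygon file has no 'islets' entry: ", path)
  islets <- lapply(obj$islets, function(is) {
    verts <- do.call(rbind, lapply(is$vertices, function(v)
      c(as.numeric(v[[1]]), as.numeric(v[[2]]))))
    list(id = as.character(is$id), polygon = IsletPolygon(verts))
  })
  list(image = as.character(obj$image %||% NA_character_), islets = islets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an islet-polygon sidecar file
#'
#' @param image image filename the polygons belong to.
#' @param islets list of \code{list(id = ..., vertices = <matrix>)} or
#'   \code{list(id = ..., polygon = IsletPolygon)}.
#' @param path destination \code{.polygons.json} path.
#' @return the path, invisibly.
#' @export
writePolygonFile <- function(image, islets, path) {
  entries <- lapply(islets, function(is) {
    v <- if (!is.null(is$polygon)) vertices(is$polygon) else is$vertices
    list(id = is$id,
         vertices = lapply(seq_len(nrow(v)), function(i) c(v[i, 1], v[i, 2])))
  })
  jsonlite::write_json(list(image = image, islets = entries), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Discover analyzable images in a folder
#'
#' Lists images with extension tif/tiff/jpg/jpeg/png (case-insensitive),
#' sorted lexicographically, and pairs each with its polygon sidecar
#' (\code{<stem>.polygons.json}) and, if present, a support image matched by
#' filename prefix from the \code{support} subfolder. Images without a
#' sidecar are kept in the listing with status \code{"skipped"} and a
#' warning; they are never silently dropped. An empty folder yields an
#' empty listing with a warning.
#'
#' @param folder directory to search.
#' @param supportDir name of the support subfolder, default
#'   \code{"support"}.
#' @return data.frame with columns \code{image}, \code{polygonFile},
#'   \code{supportImage}, \code{status} (\code{"ok"} or \code{"skipped"}).
#' @export
discoverImages <- function(folder, supportDir = "support") {
  if (!dir.exists(folder)) stop("folder not found: ", folder)
  files <- list.files(folder)
  ext <- tolower(tools::file_ext(files))
  imgs <- sort(files[ext %in% .imageExtensions], method = "radix")
  if (length(imgs) == 0) {
    warning("no images found in ", folder, call. = FALSE)
    return(data.frame(image = character(0), polygonFile = character(0),
                      supportImage = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  polyFiles <- file.path(folder, paste0(.stripExtension(imgs), ".polygons.json"))
  hasPoly <- file.exists(polyFiles)
  if (any(!hasPoly))
    warning("no polygon sidecar for: ",
            paste(imgs[!hasPoly], collapse = ", "),
            "; these images are skipped", call. = FALSE)
  support <- vapply(imgs, function(f)
    matchSupport(file.path(folder, f), file.path(folder, supportDir)),
    character(1))
  data.frame(image = file.path(folder, imgs),
             polygonFile = ifelse(hasPoly, polyFiles, NA_character_),
             supportImage = unname(support),
             status = ifelse(hasPoly, "ok", "skipped"),
             stringsAsFactors = FALSE)
}

#' Match a support image by filename prefix
#'
#' A support image (typically a DAPI nuclear stain) relates to a main image
#' when the first three characters of the filenames match. If several
#' support files share the prefix, the first match in lexicographic order is
#' used.
#'
#' @param mainImagePath path of the main image.
#' @param supportFolder folder holding support images; a missing folder
#'   yields no match.
#' @return the matched support image path, or \code{NA_character_}.
#' @export
matchSupport <- function(mainImagePath, supportFolder) {
  if (!dir.exists(supportFolder)) return(NA_character_)
  prefix <- substr(basename(mainImagePath), 1, 3)
  cand <- sort(list.files(supportFolder), method = "radix")
  hit <- cand[substr(cand, 1, 3) == prefix]
  if (length(hit) == 0) return(NA_character_)
  file.path(supportFolder, hit[1])
}

#' Analyse one image: detection plus per-islet relative radii
#'
#' Runs cell detection once on the whole image, then for every islet polygon
#' in the sidecar: validates the polygon (auto-sorting and flagging it if
#' its vertex angles are not weakly monotonic), counts islet and cell
#' pixels, computes relative radii of the detected pixel centres inside the
#' polygon, and summarises. A support image, when given, is loaded and
#' contrast-stretched exactly as the interactive display would, but its
#' pixels never enter the analysis.
#'
#' @param imagePath path of the main image.
#' @param polygonPath path of its \code{.polygons.json} sidecar.
#' @param config a \code{\linkS4class{DetectionConfig}}.
#' @param supportPath optional support image path (display-only).
#' @param verbose emit a per-islet \code{message}.
#' @return data.frame with one \code{\link{isletSummary}} row per islet.
#' @export
analyzeImage <- function(imagePath, polygonPath, config, supportPath = NULL,
                         verbose = FALSE) {
  stopifnot(is(config, "DetectionConfig"))
  image <- readRasterImage(imagePath)
  if (!is.null(supportPath) && !is.na(supportPath)) {
    sup <- readRasterImage(supportPath)
    if (length(dim(sup)) == 3L) sup <- sup[, , 1]
    invisible(enhanceSupportForDisplay(sup))  # display path only
  }
  mask <- detectCells(image, config)
  pos <- which(mask, arr.ind = TRUE)
  points <- cbind(pos[, 2] - 0.5, pos[, 1] - 0.5)  # pixel centres (x, y)
  sidecar <- readPolygonFile(polygonPath)
  rows <- lapply(sidecar$islets, function(is) {
    poly <- validatePolygon(is$polygon)
    center <- polygonCentroid(poly)
    area <- relativeArea(mask, poly)
    pp <- relativeRadii(poly, points, center = center)
    res <- isletSummary(pp, area = area, imageId = basename(imagePath),
                        isletId = is$id, stainMode = config@mode,
                        polygonWasInvalid = wasInvalid(poly))
    if (verbose)
      message(sprintf("  islet %s: %d cell px, mean rel radius %s",
                      is$id, res$n_cell_pixels,
                      ifelse(is.na(res$mean_relative_radius_pct), "NA",
                             sprintf("%.2f%%", res$mean_relative_radius_pct))))
    res
  })
  do.call(rbind, rows)
}

#' Analyse a folder of stained-section images
#'
#' Discovers images, pairs them with polygon sidecars and support images,
#' analyses every islet, and optionally exports the collected results. The
#' returned table carries run metadata (config fingerprint, timestamp,
#' package version, discovery accounting) as attributes; excluded islets
#' stay in the table with their exclusion flag set.
#'
#' @param folder directory with images and \code{.polygons.json} sidecars.
#' @param mode \code{"ihc"} or \code{"if"}.
#' @param config a \code{\linkS4class{DetectionConfig}}, a config file path
#'   readable by \code{\link{readDetectionConfig}}, or \code{NULL} for the
#'   documented defaults.
#' @param outPrefix if non-\code{NULL}, results are written to
#'   \code{<outPrefix>.csv} / \code{.xlsx} / \code{.run.json} via
#'   \code{\link{exportResults}}.
#' @param supportDir name of the support subfolder.
#' @param verbose emit per-image progress messages.
#' @return data.frame of per-islet results (possibly zero rows), with
#'   attributes \code{metadata} (list) describing the run.
#' @export
analyzeFolder <- function(folder, mode = c("ihc", "if"), config = NULL,
                          outPrefix = NULL, supportDir = "support",
                          verbose = TRUE) {
  mode <- match.arg(mode)
  if (is.null(config) || is.character(config))
    config <- readDetectionConfig(config)[[mode]]
  stopifnot(is(config, "DetectionConfig"), config@mode == mode)
  items <- discoverImages(folder, supportDir = supportDir)
  todo <- items[items$status == "ok", , drop = FALSE]
  rows <- vector("list", nrow(todo))
  for (i in seq_len(nrow(todo))) {
    if (verbose)
      message(sprintf("analyzing %s", basename(todo$image[i])))
    rows[[i]] <- analyzeImage(todo$image[i], todo$polygonFile[i], config,
                              supportPath = todo$supportImage[i],
                              verbose = verbose)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    isletSummary(new("PolarPointSet"))[0, ]
  rownames(results) <- NULL
  attr(results, "metadata") <- list(
    configHash = .configHash(.describeConfig(config)),
    config = .describeConfig(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    version = as.character(utils::packageVersion("IsletRadius")),
    nDiscovered = nrow(items), nAnalyzed = nrow(todo),
    nSkipped = sum(items$status == "skipped"))
  if (verbose)
    message(sprintf("%d image(s) discovered: %d analyzed, %d skipped",
                    nrow(items), nrow(todo),
                    sum(items$status == "skipped")))
  if (!is.null(outPrefix)) exportResults(results, outPrefix)
  results
}

.formatCsvValue <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    out <- sprintf("%.6f", x)
    out[is.na(x)] <- ""
    out
  } else {
    out <- as.character(x)
    out[is.na(out)] <- ""
    out
  }
}

#' Export a results table as CSV and XLSX
#'
#' Writes \code{<outPrefix>.csv} (UTF-8, comma-separated, numeric fields at
#' 6 decimal places) and \code{<outPrefix>.xlsx} with identical content
#' (numbers at full double precision), plus \code{<outPrefix>.run.json}
#' holding the run metadata -- config fingerprint, timestamp and package
#' version stay out of the CSV body so that repeated runs on identical
#' inputs produce byte-identical CSVs.
#'
#' @param results data.frame from \code{\link{analyzeFolder}} (zero rows
#'   allowed: a header-only CSV and a valid XLSX are still written).
#' @param outPrefix output path prefix.
#' @return named character vector with elements \code{csv}, \code{xlsx} and
#'   \code{meta}, invisibly.
#' @export
exportResults <- function(results, outPrefix) {
  stopifnot(is.data.frame(results))
  dir <- dirname(outPrefix)
  if (!dir.exists(dir))
    stop("cannot write results: directory does not exist: ", dir)
  csvPath <- paste0(outPrefix, ".csv")
  xlsxPath <- paste0(outPrefix, ".xlsx")
  metaPath <- paste0(outPrefix, ".run.json")
  cols <- lapply(results, .formatCsvValue)
  lines <- c(paste(names(results), collapse = ","),
             if (nrow(results))
               do.call(paste, c(cols, sep = ",")))
  con <- file(csvPath, open = "wb")  # fixed newlines across platforms
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  writeXlsx(results, xlsxPath)
  meta <- attr(results, "metadata") %||%
    list(version = as.character(utils::packageVersion("IsletRadius")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csvPath, xlsx = xlsxPath, meta = metaPath))
}
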