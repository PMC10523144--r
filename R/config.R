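# Detection-config file handling (INI-style: [ihc] and [if] sections) and a
# small fingerprint used to stamp result tables with the config they came
# from.

.parseIni <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[;#].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- tolower(gsub("^\\[|\\]$", "", ln))
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section))
        stop("config parse error: key outside any [section] in ", path)
      key <- tolower(trimws(sub("=.*$", "", ln)))
      val <- trimws(sub("^[^=]*=", "", ln))
      num <- suppressWarnings(as.numeric(val))
      out[[section]][[key]] <- if (is.na(num)) val else num
    } else {
      stop("config parse error: cannot parse line '", ln, "' in ", path)
    }
  }
  out
}

#' Read detection thresholds from a config file
#'
#' Parses an INI-style file with an \code{[ihc]} section (keys
#' \code{hue_lower}, \code{hue_upper}, \code{sat_lower}, \code{sat_upper},
#' \code{val_lower}, \code{val_upper}, optional \code{min_blob_size}) and an
#' \code{[if]} section (keys \code{threshold} -- a number in \code{[0, 1]}
#' or \code{otsu} -- and optional \code{min_blob_size}). Missing sections or
#' keys fall back to the documented defaults of
#' \code{\link{DetectionConfig}}. A template lives at
#' \code{system.file("extdata", "detection_default.ini", package =
#' "IsletRadius")}.
#'
#' @param path config file path, or \code{NULL} for pure defaults.
#' @return named list with elements \code{ihc} and \code{if}, each a
#'   \code{\linkS4class{DetectionConfig}}.
#' @export
readDetectionConfig <- function(path = NULL) {
  ini <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    .parseIni(path)
  }
  pick <- function(sec, key, default) {
    v <- ini[[sec]][[key]]
    if (is.null(v)) default else v
  }
  ihc <- DetectionConfig("ihc",
    hsvLower = c(pick("ihc", "hue_lower", 0),
                 pick("ihc", "sat_lower", 0.2),
                 pick("ihc", "val_lower", 0.1)),
    hsvUpper = c(pick("ihc", "hue_upper", 50),
                 pick("ihc", "sat_upper", 1),
                 pick("ihc", "val_upper", 0.95)),
    minBlobSize = pick("ihc", "min_blob_size", 0))
  iff <- DetectionConfig("if",
    ifThreshold = pick("if", "threshold", "otsu"),
    minBlobSize = pick("if", "min_blob_size", 0))
  list(ihc = ihc, "if" = iff)
}

# Polynomial fingerprint of a deparsed object; stable across sessions, used
# only to label result tables with the config that produced them.
.configHash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(s) %% 256
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.describeConfig <- function(config) {
  list(mode = config@mode, hsvLower = config@hsvLower,
       hsvUpper = config@hsvUpper,
       ifThreshold = config@ifThreshold, minBlobSize = config@minBlobSize)
}
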