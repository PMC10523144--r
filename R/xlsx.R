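# Minimal XLSX (OOXML spreadsheet) writer: one worksheet, inline strings,
# numbers stored at full double precision. Enough to mirror the CSV export
# in spreadsheet form.

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.colLetter <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]; s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      n <- (n - 1) %/% 26
    }
    out[k] <- s
  }
  out
}

.sheetCell <- function(ref, value) {
  if (is.na(value))
    return(sprintf('<c r="%s"/>', ref))
  if (is.numeric(value))
    return(sprintf('<c r="%s"><v>%s</v></c>', ref,
                   formatC(value, digits = 15, format = "g")))
  if (is.logical(value))
    return(sprintf('<c r="%s" t="b"><v>%d</v></c>', ref, as.integer(value)))
  sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
          ref, .xmlEscape(as.character(value)))
}

#' Write a data.frame as a minimal XLSX spreadsheet
#'
#' Writes a single-sheet XLSX file with a header row, inline strings for
#' character columns, full-precision doubles for numeric columns and native
#' booleans for logical columns. Intended for the result tables of
#' \code{\link{exportResults}}; it makes no attempt at styling.
#'
#' @param df a data.frame.
#' @param path destination \code{.xlsx} path.
#' @param sheetName worksheet name.
#' @return the path, invisibly.
#' @export
writeXlsx <- function(df, path, sheetName = "Results") {
  stopifnot(is.data.frame(df))
  tmp <- tempfile("xlsx")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>'), file.path(tmp, "[Content_Types].xml"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(tmp, "_rels", ".rels"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    sprintf('<sheets><sheet name="%s" sheetId="1" r:id="rId1"/></sheets>',
            .xmlEscape(sheetName)),
    '</workbook>'), file.path(tmp, "xl", "workbook.xml"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '</Relationships>'), file.path(tmp, "xl", "_rels", "workbook.xml.rels"))

  rows <- character(nrow(df) + 1L)
  header <- vapply(seq_along(df), function(j)
    .sheetCell(paste0(.colLetter(j), 1L), names(df)[j]), character(1))
  rows[1] <- sprintf('<row r="1">%s</row>', paste(header, collapse = ""))
  for (i in seq_len(nrow(df))) {
    cells <- vapply(seq_along(df), function(j)
      .sheetCell(paste0(.colLetter(j), i + 1L), df[[j]][i]), character(1))
    rows[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L,
                            paste(cells, collapse = ""))
  }
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', rows, '</sheetData>', '</worksheet>'),
    file.path(tmp, "xl", "worksheets", "sheet1.xml"))

  if (file.exists(path)) unlink(path)
  zip::zipr(zipfile = path,
            files = file.path(tmp, c("[Content_Types].xml", "_rels", "xl")))
  invisible(path)
}
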