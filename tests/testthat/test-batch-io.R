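writeBlank <- function(path, color = FALSE) {
  img <- if (color) array(0.5, c(8, 8, 3)) else matrix(0.5, 8, 8)
  writeRasterImage(img, path)
}

test_that("discovery lists images case-insensitively and flags missing sidecars", {
  d <- withr::local_tempdir()
  writeBlank(file.path(d, "a.tif"))
  writeBlank(file.path(d, "b.png"))
  writeLines("not an image", file.path(d, "c.txt"))
  writeBlank(file.path(d, "A01.TIF"))
  writePolygonFile("a.tif", list(list(id = "1", vertices = rbind(
    c(1, 1), c(7, 1), c(4, 7)))), file.path(d, "a.polygons.json"))
  expect_warning(items <- discoverImages(d), "no polygon sidecar")
  expect_equal(basename(items$image), c("A01.TIF", "a.tif", "b.png"))
  expect_equal(items$status, c("skipped", "ok", "skipped"))

  empty <- withr::local_tempdir()
  expect_warning(none <- discoverImages(empty), "no images")
  expect_equal(nrow(none), 0L)
})

test_that("support images match on the first three filename characters", {
  d <- withr::local_tempdir()
  sup <- file.path(d, "support")
  dir.create(sup)
  file.create(file.path(sup, "A01_dapi.tif"))
  expect_equal(basename(matchSupport(file.path(d, "A01_ins.tif"), sup)),
               "A01_dapi.tif")
  # non-unique prefix: first match in lexicographic order
  file.create(file.path(sup, "A01_a.tif"), file.path(sup, "A01_b.tif"))
  expect_equal(basename(matchSupport(file.path(d, "A01_ins.tif"), sup)),
               "A01_a.tif")
  expect_true(is.na(matchSupport(file.path(d, "B02_ins.tif"), sup)))
  expect_true(is.na(matchSupport(file.path(d, "A01_ins.tif"),
                                 file.path(d, "nosuchdir"))))
})

test_that("display contrast stretch spans the range and spares constants", {
  const <- matrix(0.3, 5, 5)
  expect_identical(enhanceSupportForDisplay(const), const)
  img <- matrix(seq(10, 200) / 255, ncol = 1)
  out <- enhanceSupportForDisplay(img)
  expect_equal(range(out), c(0, 1))
})

test_that("polygon sidecars round-trip through JSON", {
  d <- withr::local_tempdir()
  v <- rbind(c(1.5, 2.25), c(10, 2), c(9, 11.125), c(2, 10))
  p <- file.path(d, "img.polygons.json")
  writePolygonFile("img.tif", list(list(id = "7", vertices = v)), p)
  back <- readPolygonFile(p)
  expect_equal(back$image, "img.tif")
  expect_equal(back$islets[[1]]$id, "7")
  expect_equal(unname(vertices(back$islets[[1]]$polygon)), unname(v))
})

test_that("CSV export has the fixed schema and round-trips to 6 decimals", {
  d <- withr::local_tempdir()
  rel <- list(c(20, 40, 61.23456789), c(30, 120), numeric(0))
  rows <- do.call(rbind, lapply(seq_along(rel), function(i) {
    r <- rel[[i]]
    isletSummary(new("PolarPointSet", x = r, y = numeric(length(r)),
                     theta = numeric(length(r)), r = r,
                     rBoundary = rep(100, length(r)), relRadius = r,
                     nOutside = 0L),
                 imageId = "img.tif", isletId = as.character(i),
                 stainMode = "ihc")
  }))
  paths <- exportResults(rows, file.path(d, "out"))
  lines <- readLines(paths["csv"])
  expect_length(lines, 4L)   # header + 3 islets, excluded one included
  expect_equal(lines[1], paste("image_id,islet_id,stain_mode,n_cell_pixels",
    "n_islet_pixels,relative_area_pct,mean_relative_radius_pct,n_included",
    "n_excluded,pct_excluded,polygon_was_invalid,excluded_no_staining",
    sep = ","))
  back <- utils::read.csv(paths["csv"])
  expect_equal(back$mean_relative_radius_pct,
               round(rows$mean_relative_radius_pct, 6))
  expect_equal(back$pct_excluded, round(rows$pct_excluded, 6))
  expect_equal(back$excluded_no_staining, c(FALSE, FALSE, TRUE))

  # spreadsheet mirror holds identical content at full precision
  skip_if_not_installed("readxl")
  x <- readxl::read_xlsx(paths["xlsx"])
  expect_equal(nrow(x), 3L)
  expect_equal(names(x), names(rows))
  expect_equal(as.numeric(x$mean_relative_radius_pct),
               rows$mean_relative_radius_pct)
})

test_that("zero-row results still export a header-only CSV and valid XLSX", {
  d <- withr::local_tempdir()
  empty <- isletSummary(new("PolarPointSet"))[0, ]
  paths <- exportResults(empty, file.path(d, "none"))
  expect_length(readLines(paths["csv"]), 1L)
  skip_if_not_installed("readxl")
  x <- readxl::read_xlsx(paths["xlsx"])
  expect_equal(nrow(x), 0L)
  expect_equal(ncol(x), 12L)
})

test_that("export to a missing directory fails with the path in the message", {
  expect_error(exportResults(isletSummary(new("PolarPointSet")),
                             "/nonexistent-dir-xyz/out"),
               "nonexistent-dir-xyz")
})

test_that("only the first frame of a multi-frame image is analysed", {
  d <- withr::local_tempdir()
  p <- file.path(d, "stack.tif")
  stack <- EBImage::Image(array(c(rep(0.2, 36), rep(0.9, 36)), c(6, 6, 2)))
  EBImage::writeImage(stack, p)
  expect_warning(img <- readRasterImage(p), "first frame")
  expect_equal(dim(img), c(6, 6))
  expect_equal(unique(as.vector(round(img, 1))), 0.2)
})
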