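test_that("ESRI ASCII grids round-trip through write and read", {
  g <- tinyGrid()
  f <- withr::local_tempfile(fileext = ".asc")
  writeEsriAscii(g, getLayer(g, "envA"), f)
  r <- readEsriAscii(f)
  expect_identical(r$nRows, 3L)
  expect_identical(r$nCols, 4L)
  expect_equal(r$cellSizeDeg, 1)
  expect_equal(r$values, getLayer(g, "envA"))
})

test_that("loadEnvStack stacks aligned rasters and unions no-data masks", {
  g <- tinyGrid()
  d <- withr::local_tempdir()
  a <- getLayer(g, "envA"); b <- getLayer(g, "envB")
  # layer A misses cells 4, 9 (the grid mask); B misses 1 and 12 as well
  b[c(1, 12)] <- NA
  writeEsriAscii(g, a, file.path(d, "a.asc"))
  writeEsriAscii(g, b, file.path(d, "b.asc"))
  st <- loadEnvStack(file.path(d, c("a.asc", "b.asc")), c("a", "b"))
  expect_identical(layerNames(st), c("a", "b"))
  expect_identical(validCells(st), setdiff(1:12, c(1, 4, 9, 12)))
  expect_true(all(is.na(st@layers[c(1, 4, 9, 12), ])))
})

test_that("loadEnvStack rejects rasters with mismatched geometry and names the layer", {
  g <- tinyGrid()
  g2 <- envGrid(list(x = rep(1, 8)), nRows = 2, nCols = 4,
                cellSizeArcmin = 60, origin = c(0, 0))
  d <- withr::local_tempdir()
  writeEsriAscii(g, getLayer(g, "envA"), file.path(d, "a.asc"))
  writeEsriAscii(g2, getLayer(g2, "x"), file.path(d, "b.asc"))
  expect_error(loadEnvStack(file.path(d, c("a.asc", "b.asc")), c("a", "b")),
               "geometry mismatch.*b")
})

test_that("gridOccurrences deduplicates points within a cell and drops masked points", {
  g <- tinyGrid()  # 1-degree cells, origin (0,0), 3 rows so north edge = 3
  # two points in the same cell (row 1, col 1 -> cell 1), one in cell 2
  pts <- data.frame(lon = c(0.2, 0.8, 1.5), lat = c(2.5, 2.7, 2.5))
  ps <- gridOccurrences(pts, g)
  expect_identical(presenceCells(ps), c(1L, 2L))
  # cell 4 (row 1, col 4) is masked: its point is dropped with a message
  pts2 <- data.frame(lon = c(3.5, 0.2), lat = c(2.5, 2.5))
  expect_message(ps2 <- gridOccurrences(pts2, g), "dropped")
  expect_identical(presenceCells(ps2), 1L)
  # empty input is an empty set, not an error
  expect_length(presenceCells(gridOccurrences(pts[0, ], g)), 0L)
})

test_that("gridOccurrences matches brute-force binning on random points", {
  g <- envGrid(list(z = rep(0, 100)), nRows = 10, nCols = 10,
               cellSizeArcmin = 60, origin = c(0, 0))
  withr::with_seed(42, {
    lon <- runif(100, 0, 10); lat <- runif(100, 0, 10)
  })
  ps <- gridOccurrences(data.frame(lon = lon, lat = lat), g)
  # independent binning: row from the top edge, col from the left edge
  row <- floor(10 - lat) + 1; col <- floor(lon) + 1
  expect_identical(presenceCells(ps),
                   sort(unique(as.integer((row - 1) * 10 + col))))
})

test_that("gridOccurrences is idempotent on its own cell centroids", {
  w <- smallWorld(seed = 3)
  ps <- w$presences
  cen <- cellCentroids(w$grid, presenceCells(ps))
  ps2 <- gridOccurrences(data.frame(lon = cen$lon, lat = cen$lat), w$grid,
                         taxon = ps@taxon)
  expect_identical(presenceCells(ps2), presenceCells(ps))
})

test_that("cell width at the equator follows the 40,075 km circumference", {
  expect_equal(round(cellWidthAtEquator(10), 1), 18.6)
  expect_equal(round(cellWidthAtEquator(60), 1), 111.3)
  expect_error(cellWidthAtEquator(0), "positive")
  expect_error(cellWidthAtEquator(-5), "positive")
})

test_that("background sampling is uniform, seeded, exhaustive at n = valid cells", {
  g <- tinyGrid()
  expect_identical(sampleBackground(g, 0, seed = 1), integer())
  expect_identical(sampleBackground(g, sum(g@mask), seed = 1), validCells(g))
  expect_error(sampleBackground(g, sum(g@mask) + 1, seed = 1), "valid cells")
  expect_identical(sampleBackground(g, 5, seed = 9),
                   sampleBackground(g, 5, seed = 9))
  # presence cells are not excluded: with n = all valid cells every
  # presence cell is in the draw
  w <- smallWorld(seed = 4)
  all <- sampleBackground(w$grid, sum(w$grid@mask), seed = 2)
  expect_true(all(presenceCells(w$presences) %in% all))
})

test_that("background draws pass a stratified chi-square uniformity check", {
  g <- envGrid(list(z = rep(0, 10000)), nRows = 100, nCols = 100,
               cellSizeArcmin = 10, origin = c(0, 0))
  strat <- ((validCells(g) - 1L) %/% 1000L) + 1L  # 10 row strata
  pass <- vapply(1:100, function(k) {
    s <- sampleBackground(g, 5000, seed = k)
    tab <- table(factor(((s - 1L) %/% 1000L) + 1L, levels = 1:10))
    suppressWarnings(stats::chisq.test(tab)$p.value) > 0.01
  }, TRUE)
  expect_gte(mean(pass), 0.95)
})

test_that("no operation returns a masked cell", {
  w <- smallWorld(seed = 5)
  g <- w$grid
  expect_true(all(g@mask[sampleBackground(g, 500, seed = 1)]))
  expect_true(all(g@mask[presenceCells(w$presences)]))
  pts <- cellCentroids(g, validCells(g)[1:20])
  expect_true(all(g@mask[presenceCells(gridOccurrences(pts, g))]))
})
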