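#' Construct an EnvGrid from per-cell layer values
#'
#' Low-level constructor used by the readers and the simulator. Cell IDs
#' are row-major with row 1 at the northern edge.
#'
#' @param layers named list of numeric vectors (length `nRows * nCols`) or
#'   a cells-by-variables matrix with column names.
#' @param nRows,nCols grid dimensions.
#' @param cellSizeArcmin cell size in arc-minutes.
#' @param origin (lon, lat) of the lower-left grid corner, decimal degrees.
#' @param mask optional logical vector; defaults to cells finite in every
#'   layer.
#' @return an [EnvGrid].
#' @export
envGrid <- function(layers, nRows, nCols, cellSizeArcmin = 10,
                    origin = c(0, 0), mask = NULL) {
  if (is.list(layers)) {
    nm <- names(layers)
    layers <- do.call(cbind, layers)
    colnames(layers) <- nm
  }
  storage.mode(layers) <- "double"
  if (is.null(mask))
    mask <- rowSums(!is.finite(layers)) == 0L
  layers[!mask, ] <- NA_real_
  new("EnvGrid", nRows = as.integer(nRows), nCols = as.integer(nCols),
      cellSizeArcmin = as.numeric(cellSizeArcmin),
      origin = as.numeric(origin), layers = layers, mask = as.logical(mask))
}

#' Construct a PresenceSet
#'
#' @param cells integer cell IDs (duplicates collapse: set semantics).
#' @param taxon taxon label.
#' @param grid optional [EnvGrid]; if given, cells must be valid cells.
#' @return a [PresenceSet].
#' @export
presenceSet <- function(cells, taxon = "species", grid = NULL) {
  cells <- sort(unique(as.integer(cells)))
  if (!is.null(grid) && length(cells) &&
      (any(cells > nCells(grid)) || any(!grid@mask[cells])))
    stop("presence cells must be valid (unmasked) cells of the grid")
  new("PresenceSet", cells = cells, taxon = as.character(taxon))
}

## ---- ESRI ASCII grid I/O -------------------------------------------------
## Plain-text raster format: a 6-line header (ncols, nrows, xllcorner,
## yllcorner, cellsize, NODATA_value) followed by rows north to south.

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return list with `values` (numeric vector, row-major from the northern
#'   row, no-data as `NA`) and the header fields `nRows`, `nCols`,
#'   `xll`, `yll`, `cellSizeDeg`.
#' @export
readEsriAscii <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  for (i in 1:6) {
    ln <- strsplit(trimws(readLines(con, n = 1L)), "\\s+")[[1]]
    hdr[[tolower(ln[1])]] <- as.numeric(ln[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path)
  vals <- scan(con, what = numeric(), quiet = TRUE)
  n <- hdr$nrows * hdr$ncols
  if (length(vals) != n)
    stop("expected ", n, " cell values in ", path, ", found ", length(vals))
  nd <- hdr[["nodata_value"]]
  if (!is.null(nd) && !is.na(nd)) vals[vals == nd] <- NA_real_
  list(values = vals, nRows = as.integer(hdr$nrows),
       nCols = as.integer(hdr$ncols), xll = hdr$xllcorner,
       yll = hdr$yllcorner, cellSizeDeg = hdr$cellsize)
}

#' Write a per-cell map as an ESRI ASCII grid
#'
#' @param grid the [EnvGrid] supplying geometry.
#' @param values numeric vector of length `nCells(grid)` (`NA` allowed).
#' @param path output file.
#' @param nodata no-data sentinel written for `NA` cells.
#' @param digits significant digits for cell values.
#' @export
writeEsriAscii <- function(grid, values, path, nodata = -9999,
                           digits = 7) {
  stopifnot(length(values) == nCells(grid))
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("ncols %d\nnrows %d\nxllcorner %.10g\nyllcorner %.10g\ncellsize %.10g\nNODATA_value %g\n",
              grid@nCols, grid@nRows, grid@origin[1], grid@origin[2],
              grid@cellSizeArcmin / 60, nodata), file = con)
  v <- signif(values, digits)
  v[is.na(v)] <- nodata
  m <- matrix(v, nrow = grid@nRows, ncol = grid@nCols, byrow = TRUE)
  writeLines(apply(m, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Load a stack of aligned rasters into an EnvGrid
#'
#' Reads one ESRI ASCII grid per variable and stacks them on a shared
#' geometry. The mask keeps only cells valid (non-no-data) in *every*
#' layer.
#'
#' @param paths character vector of raster files.
#' @param variableNames one name per file (defaults to file base names).
#' @return an [EnvGrid].
#' @export
loadEnvStack <- function(paths, variableNames = NULL) {
  stopifnot(length(paths) >= 1L)
  if (is.null(variableNames))
    variableNames <- tools::file_path_sans_ext(basename(paths))
  stopifnot(length(variableNames) == length(paths))
  ref <- readEsriAscii(paths[1])
  layers <- matrix(NA_real_, ref$nRows * ref$nCols, length(paths),
                   dimnames = list(NULL, variableNames))
  layers[, 1] <- ref$values
  for (i in seq_along(paths)[-1]) {
    r <- readEsriAscii(paths[i])
    same <- r$nRows == ref$nRows && r$nCols == ref$nCols &&
      isTRUE(all.equal(c(r$xll, r$yll, r$cellSizeDeg),
                       c(ref$xll, ref$yll, ref$cellSizeDeg), tolerance = 1e-9))
    if (!same)
      stop("raster geometry mismatch in layer '", variableNames[i],
           "' (", paths[i], ")")
    layers[, i] <- r$values
  }
  envGrid(layers, ref$nRows, ref$nCols, cellSizeArcmin = ref$cellSizeDeg * 60,
          origin = c(ref$xll, ref$yll))
}

## ---- occurrences ---------------------------------------------------------

#' Read an occurrence table (lon, lat[, clade]) from CSV
#'
#' @param path CSV with columns `lon`, `lat` and optionally `clade`.
#' @return data.frame of occurrence points.
#' @export
readOccurrences <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lon", "lat") %in% names(d)))
    stop("occurrence CSV must have columns lon, lat")
  if (any(d$lon < -180 | d$lon > 180) || any(d$lat < -90 | d$lat > 90))
    stop("coordinates out of range: lon in [-180, 180], lat in [-90, 90]")
  d
}

#' Map geographic points to grid cell IDs
#'
#' Binning is half-open: a point on a cell boundary belongs to the cell to
#' its south-east. Points outside the grid extent map to `NA`.
#'
#' @param grid an [EnvGrid].
#' @param lon,lat coordinate vectors in decimal degrees.
#' @return integer cell IDs (`NA` outside the extent).
#' @export
pointToCell <- function(grid, lon, lat) {
  cellDeg <- grid@cellSizeArcmin / 60
  north <- grid@origin[2] + grid@nRows * cellDeg
  col <- floor((lon - grid@origin[1]) / cellDeg) + 1
  row <- floor((north - lat) / cellDeg) + 1
  bad <- col < 1 | col > grid@nCols | row < 1 | row > grid@nRows
  id <- (row - 1) * grid@nCols + col
  id[bad] <- NA_integer_
  as.integer(id)
}

#' Cell centre coordinates
#'
#' @param grid an [EnvGrid].
#' @param cells integer cell IDs.
#' @return data.frame with `lon`, `lat` of cell centroids.
#' @export
cellCentroids <- function(grid, cells) {
  cellDeg <- grid@cellSizeArcmin / 60
  north <- grid@origin[2] + grid@nRows * cellDeg
  row <- (cells - 1L) %/% grid@nCols + 1L
  col <- (cells - 1L) %% grid@nCols + 1L
  data.frame(lon = grid@origin[1] + (col - 0.5) * cellDeg,
             lat = north - (row - 0.5) * cellDeg)
}

#' Convert occurrence points to grid-cell presences
#'
#' A grid cell is recorded as a presence regardless of whether one or
#' several occurrence points fall within its limits (set semantics).
#' Points landing in masked cells or outside the grid are dropped with a
#' message reporting the count.
#'
#' @param points data.frame with `lon`, `lat` and optionally `clade`.
#' @param grid an [EnvGrid].
#' @param cladeFilter optional clade label; keeps only matching points.
#' @param taxon label for the resulting [PresenceSet].
#' @return a [PresenceSet] of distinct occupied valid cells (possibly
#'   empty).
#' @export
gridOccurrences <- function(points, grid, cladeFilter = NULL,
                            taxon = if (is.null(cladeFilter)) "species"
                                    else paste0("clade", cladeFilter)) {
  if (!is.null(cladeFilter)) {
    if (is.null(points$clade)) stop("points carry no clade column")
    points <- points[!is.na(points$clade) & points$clade == cladeFilter, ,
                     drop = FALSE]
  }
  if (nrow(points) == 0L)
    return(presenceSet(integer(), taxon = taxon))
  ids <- pointToCell(grid, points$lon, points$lat)
  keep <- !is.na(ids) & grid@mask[ids]
  keep[is.na(keep)] <- FALSE
  nDropped <- sum(!keep)
  if (nDropped > 0L)
    message(nDropped, " point(s) fell in masked cells or outside the grid and were dropped")
  presenceSet(unique(ids[keep]), taxon = taxon, grid = grid)
}

#' Equatorial width of a grid cell
#'
#' Arc length spanned at the equator by a cell of the given angular size,
#' using a 40,075 km equatorial circumference: a 10 arc-minute cell spans
#' 18.6 km.
#'
#' @param cellSizeArcmin cell size in arc-minutes (> 0).
#' @return width in km.
#' @export
cellWidthAtEquator <- function(cellSizeArcmin) {
  if (!is.numeric(cellSizeArcmin) || any(cellSizeArcmin <= 0))
    stop("cellSizeArcmin must be positive")
  40075 * cellSizeArcmin / (360 * 60)
}

#' Sample background cells
#'
#' Draws `n` distinct valid cells uniformly without replacement. Presence
#' cells are *not* excluded: background data represent the available
#' environment, not absences.
#'
#' @param grid an [EnvGrid].
#' @param n number of cells (`0 <= n <=` number of valid cells).
#' @param seed integer seed; the draw is reproducible and leaves the global
#'   RNG untouched.
#' @return sorted integer vector of cell IDs.
#' @export
sampleBackground <- function(grid, n, seed = 1) {
  ok <- validCells(grid)
  if (n > length(ok))
    stop("requested ", n, " background cells but only ", length(ok),
         " valid cells exist")
  if (n == 0L) return(integer())
  sort(withr::with_seed(as.integer(seed), sample(ok, n)))
}

#' Write a PresenceSet as a CSV of cell row/col
#'
#' @param x a [PresenceSet].
#' @param grid the [EnvGrid] defining the geometry.
#' @param path output CSV path.
#' @export
writePresenceCSV <- function(x, grid, path) {
  cells <- presenceCells(x)
  row <- (cells - 1L) %/% grid@nCols + 1L
  col <- (cells - 1L) %% grid@nCols + 1L
  utils::write.csv(data.frame(cell = cells, row = row, col = col),
                   path, row.names = FALSE)
  invisible(path)
}
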