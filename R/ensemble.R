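#' Build a MapStack from aligned suitability maps
#'
#' @param grid the shared [EnvGrid].
#' @param maps named list of per-cell suitability vectors (as returned by
#'   [predictMap()]), or a cells-by-members matrix with column names.
#' @return a [MapStack].
#' @export
mapStack <- function(grid, maps) {
  if (is.list(maps)) {
    nm <- names(maps)
    maps <- do.call(cbind, maps)
    colnames(maps) <- nm
  }
  new("MapStack", grid = grid, scores = maps)
}

#' Consensus map across ensemble members
#'
#' Cellwise summary of the member maps: `median` (the default reported
#' consensus), `mean`, or `pca1` — the first principal-component scores of
#' the cells-by-members matrix (members centered), sign-oriented so the
#' axis correlates positively with the cellwise mean, and linearly
#' rescaled to `[0, 1]`. The first axis captures the dominant shared
#' pattern, i.e. the agreement between models.
#'
#' @param stack a [MapStack].
#' @param method `"median"`, `"mean"` or `"pca1"`.
#' @return per-cell consensus vector (`NA` on masked cells).
#' @export
consensusMap <- function(stack, method = c("median", "mean", "pca1")) {
  method <- match.arg(method)
  ok <- stack@grid@mask
  X <- stack@scores[ok, , drop = FALSE]
  val <- switch(method,
    mean = rowMeans(X),
    median = apply(X, 1L, stats::median),
    pca1 = {
      pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
      s <- pc$x[, 1]
      if (stats::cor(s, rowMeans(X)) < 0) s <- -s
      rescaleUnit(s)
    })
  out <- rep(NA_real_, nCells(stack@grid))
  out[ok] <- val
  out
}

#' Share of variance carried by the first PCA axis of a stack
#'
#' @param stack a [MapStack].
#' @return percentage of total between-member variance on axis 1.
#' @export
pca1VarianceShare <- function(stack) {
  X <- stack@scores[stack@grid@mask, , drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  100 * pc$sdev[1]^2 / sum(pc$sdev^2)
}

#' Between-member variance map
#'
#' Cellwise sample variance (denominator n - 1) across the ensemble
#' members: the map of predictive uncertainty.
#'
#' @param stack a [MapStack].
#' @return per-cell variance vector (`NA` on masked cells).
#' @export
varianceMap <- function(stack) {
  ok <- stack@grid@mask
  X <- stack@scores[ok, , drop = FALSE]
  out <- rep(NA_real_, nCells(stack@grid))
  m <- rowMeans(X)
  out[ok] <- rowSums((X - m)^2) / (ncol(X) - 1)
  out
}

#' Binarize a suitability map at a threshold
#'
#' Cells with score `>= threshold` become 1, others 0 (`NA` preserved).
#'
#' @param map per-cell suitability vector.
#' @param threshold cut-off (typically the MST threshold).
#' @return integer 0/1 vector.
#' @export
binarizeMap <- function(map, threshold) {
  out <- rep(NA_integer_, length(map))
  ok <- !is.na(map)
  out[ok] <- as.integer(map[ok] >= threshold)
  out
}

#' Four-class range-change map
#'
#' Combines binarized current and future range maps cellwise:
#' in range now and later = `stable`; now only = `contraction`; later
#' only = `expansion`; never = `absent`.
#'
#' @param grid the shared [EnvGrid].
#' @param currentBin,futureBin 0/1 vectors from [binarizeMap()].
#' @return a [RangeChangeMap].
#' @export
rangeChange <- function(grid, currentBin, futureBin) {
  stopifnot(length(currentBin) == nCells(grid),
            length(futureBin) == nCells(grid))
  lv <- c("stable", "contraction", "expansion", "absent")
  cls <- rep(NA_character_, nCells(grid))
  ok <- grid@mask
  cls[ok & currentBin == 1L & futureBin == 1L] <- "stable"
  cls[ok & currentBin == 1L & futureBin == 0L] <- "contraction"
  cls[ok & currentBin == 0L & futureBin == 1L] <- "expansion"
  cls[ok & currentBin == 0L & futureBin == 0L] <- "absent"
  new("RangeChangeMap", grid = grid, classes = factor(cls, levels = lv))
}

#' Write per-class cell counts of a range-change map as CSV
#'
#' @param x a [RangeChangeMap].
#' @param path output CSV path.
#' @export
writeClassCountsCSV <- function(x, path) {
  ct <- classCounts(x)
  utils::write.csv(data.frame(class = names(ct), cells = as.integer(ct)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Plot a per-cell map
#'
#' Quick base-graphics view of a suitability, variance or range-change
#' map.
#'
#' @param grid an [EnvGrid].
#' @param values per-cell numeric vector (or a [RangeChangeMap]).
#' @param main plot title.
#' @param col colour palette.
#' @export
plotMap <- function(grid, values, main = "",
                    col = grDevices::hcl.colors(64, "viridis")) {
  if (methods::is(values, "RangeChangeMap")) {
    values <- as.integer(values@classes)
    col <- c("black", "blue", "red", "yellow")
  }
  m <- matrix(values, nrow = grid@nRows, ncol = grid@nCols, byrow = TRUE)
  graphics::image(t(m)[, grid@nRows:1], col = col, axes = FALSE, main = main,
                  useRaster = TRUE)
  invisible(NULL)
}
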