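#' Number of cells in a grid
#' @param x an [EnvGrid].
#' @return integer, `nRows * nCols`.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname nCells
#' @export
setMethod("nCells", "EnvGrid", function(x) x@nRows * x@nCols)

#' Valid (unmasked) cell IDs
#' @param x an [EnvGrid].
#' @return sorted integer vector of valid cell IDs.
#' @export
setGeneric("validCells", function(x) standardGeneric("validCells"))

#' @rdname validCells
#' @export
setMethod("validCells", "EnvGrid", function(x) which(x@mask))

#' Layer (variable) names of a grid
#' @param x an [EnvGrid].
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname layerNames
#' @export
setMethod("layerNames", "EnvGrid", function(x) colnames(x@layers))

#' Extract one layer as a per-cell vector
#' @param x an [EnvGrid].
#' @param name layer name.
#' @return numeric vector of length `nCells(x)`, `NA` on masked cells.
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))

#' @rdname getLayer
#' @export
setMethod("getLayer", "EnvGrid", function(x, name) {
  if (!name %in% colnames(x@layers))
    stop("no layer named '", name, "'")
  x@layers[, name]
})

#' Presence cells of a PresenceSet
#' @param x a [PresenceSet].
#' @export
setGeneric("presenceCells", function(x) standardGeneric("presenceCells"))

#' @rdname presenceCells
#' @export
setMethod("presenceCells", "PresenceSet", function(x) x@cells)

#' Predict a suitability map on a grid
#'
#' Applies a fitted [SuitabilityModel] to every valid cell of an [EnvGrid]
#' carrying the model's variables. All families return values in `[0, 1]`;
#' the Mahalanobis family is linearly rescaled over the valid cells of the
#' target grid (see [rescaleUnit()]), so each predicted map spans `[0, 1]`.
#'
#' @param model a fitted [SuitabilityModel].
#' @param grid an [EnvGrid] with the model's variables among its layers.
#' @return numeric vector of length `nCells(grid)`; `NA` on masked cells.
#' @export
setGeneric("predictMap", function(model, grid) standardGeneric("predictMap"))

#' Summary of an EvalReport
#' @param x an [EvalReport].
#' @return data.frame with columns `metric`, `mean`, `sd` (sample SD across
#'   repeats) for AUC, sensitivity, specificity and threshold.
#' @export
setGeneric("evalSummary", function(x) standardGeneric("evalSummary"))

#' @rdname evalSummary
#' @export
setMethod("evalSummary", "EvalReport", function(x) {
  m <- c("auc", "sensitivity", "specificity", "threshold")
  data.frame(
    metric = m,
    mean = vapply(m, function(i) mean(x@repeats[[i]]), 0),
    sd = vapply(m, function(i) stats::sd(x@repeats[[i]]), 0),
    row.names = NULL
  )
})

#' Per-class cell counts of a range-change map
#' @param x a [RangeChangeMap].
#' @return named integer vector over the four classes; sums to the number
#'   of valid cells.
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname classCounts
#' @export
setMethod("classCounts", "RangeChangeMap", function(x) {
  tab <- table(x@classes[x@grid@mask])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
})

setMethod("show", "EnvGrid", function(object) {
  cat("EnvGrid:", object@nRows, "x", object@nCols, "cells,",
      object@cellSizeArcmin, "arcmin resolution\n")
  cat("  origin (lon, lat):", object@origin[1], object@origin[2], "\n")
  cat("  layers:", paste(colnames(object@layers), collapse = ", "), "\n")
  cat("  valid cells:", sum(object@mask), "of", nCells(object), "\n")
})

setMethod("show", "PresenceSet", function(object) {
  cat("PresenceSet '", object@taxon, "': ", length(object@cells),
      " presence cells\n", sep = "")
})

setMethod("show", "SuitabilityModel", function(object) {
  cat("SuitabilityModel [", object@family, "] on ",
      length(object@variables), " variables: ",
      paste(object@variables, collapse = ", "),
      if (object@supportsWeights) " (weighted)" else " (presence-only)",
      "\n", sep = "")
})

setMethod("show", "MapStack", function(object) {
  cat("MapStack:", ncol(object@scores), "members on",
      sum(object@grid@mask), "valid cells\n")
  cat("  members:", paste(colnames(object@scores), collapse = ", "), "\n")
})

setMethod("show", "EvalReport", function(object) {
  s <- evalSummary(object)
  cat("EvalReport [", object@family, ", prevalence ", object@phi, "]: ",
      object@nRepeats, " repeats\n", sep = "")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
})

setMethod("show", "RangeChangeMap", function(object) {
  cat("RangeChangeMap:\n")
  print(classCounts(object))
})

setMethod("show", "OMIResult", function(object) {
  cat("OMIResult:", length(object@taxa), "taxa,",
      ncol(object@axes), "axes\n")
  cat("  axis variance share (%):",
      paste(sprintf("%.1f", object@varianceShare), collapse = ", "), "\n")
  for (i in seq_along(object@taxa))
    cat(sprintf("  %s: OMI = %.3f, specialization p = %.4g\n",
                object@taxa[i], object@omiStat[i], object@specializationP[i]))
})

setMethod("show", "VirtualSpeciesConfig", function(object) {
  cat("VirtualSpeciesConfig:\n")
  cat("  true variables:", paste(object@trueVariables, collapse = ", "), "\n")
  cat("  beta0:", object@beta0, " linear:",
      paste(object@betaLinear, collapse = ", "), " quadratic:",
      paste(object@betaQuadratic, collapse = ", "), "\n")
  cat("  clade offset:", object@cladeOffset, "SD along",
      object@cladeGradient, "\n")
  cat("  presences:", object@nPresence, " clades:",
      paste(object@cladeSizes, collapse = "/"), "\n")
})
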