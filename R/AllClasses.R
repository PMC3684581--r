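#' @import methods
NULL

#' EnvGrid: a masked multi-layer environmental raster
#'
#' An `EnvGrid` holds one or more co-registered environmental layers on a
#' regular geographic (lat/lon) grid, together with a shared land mask.
#' Cells are identified by integer IDs in row-major order, row 1 at the
#' northern edge: `id = (row - 1) * nCols + col`. Layer values are stored as
#' a cells-by-variables matrix; masked (sea / no-data) cells are `NA` in
#' every layer.
#'
#' @slot nRows,nCols integer grid dimensions.
#' @slot cellSizeArcmin cell size in arc-minutes (e.g. 10 for a 10-minute
#'   global climate grid).
#' @slot origin numeric length-2, (lon, lat) of the lower-left (south-west)
#'   grid corner, in decimal degrees.
#' @slot layers numeric matrix, `nRows * nCols` rows, one named column per
#'   environmental variable.
#' @slot mask logical vector of length `nRows * nCols`; `TRUE` marks a valid
#'   (land) cell.
#'
#' @seealso [loadEnvStack()], [makeEnvLayers()], [getLayer()], [validCells()]
#' @export
setClass("EnvGrid",
  representation(
    nRows = "integer",
    nCols = "integer",
    cellSizeArcmin = "numeric",
    origin = "numeric",
    layers = "matrix",
    mask = "logical"
  )
)

setValidity("EnvGrid", function(object) {
  n <- object@nRows * object@nCols
  msg <- character()
  if (length(object@origin) != 2L)
    msg <- c(msg, "origin must be (lon, lat) of the lower-left corner")
  if (object@cellSizeArcmin <= 0)
    msg <- c(msg, "cellSizeArcmin must be positive")
  if (nrow(object@layers) != n)
    msg <- c(msg, "layers must have nRows * nCols rows")
  if (length(object@mask) != n)
    msg <- c(msg, "mask must have nRows * nCols entries")
  nm <- colnames(object@layers)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    msg <- c(msg, "layer names must be unique and non-empty")
  if (nrow(object@layers) == n && length(object@mask) == n) {
    if (any(!is.na(object@layers[!object@mask, , drop = FALSE])))
      msg <- c(msg, "masked-out cells must carry no values in any layer")
    if (any(!is.finite(object@layers[object@mask, , drop = FALSE])))
      msg <- c(msg, "valid cells must be finite in every layer")
  }
  if (length(msg)) msg else TRUE
})

#' PresenceSet: grid cells occupied by a taxon
#'
#' The set of distinct grid-cell IDs recorded as presences for one taxon
#' (the species as a whole, or one of its clades). Set semantics: a cell is
#' a presence regardless of how many occurrence points fell inside it.
#'
#' @slot cells sorted integer vector of distinct cell IDs.
#' @slot taxon single character label.
#'
#' @seealso [gridOccurrences()], [samplePresences()]
#' @export
setClass("PresenceSet",
  representation(cells = "integer", taxon = "character")
)

setValidity("PresenceSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@cells)) msg <- c(msg, "cells must be distinct")
  if (is.unsorted(object@cells)) msg <- c(msg, "cells must be sorted")
  if (length(object@cells) && any(object@cells < 1L))
    msg <- c(msg, "cell IDs must be positive")
  if (length(object@taxon) != 1L) msg <- c(msg, "taxon must be a single label")
  if (length(msg)) msg else TRUE
})

#' SuitabilityModel: common interface of the eight model families
#'
#' Virtual parent of the fitted suitability models. Every subclass supports
#' [predictMap()], returning a per-cell suitability in `[0, 1]` on any
#' [EnvGrid] carrying the model's variables; prediction is deterministic
#' given the fitted state.
#'
#' @slot family model family label, one of `"GAM"`, `"GLM"`, `"CART"`,
#'   `"BRT"`, `"BIOCLIM"`, `"DOMAIN"`, `"MAHAL"`, `"MAXENT"`.
#' @slot variables ordered predictor names used at fit time.
#' @slot supportsWeights whether the family uses prevalence weights
#'   (presence-only families do not).
#'
#' @seealso [fitModel()], [predictMap()]
#' @export
setClass("SuitabilityModel",
  representation("VIRTUAL",
    family = "character",
    variables = "character",
    supportsWeights = "logical"
  )
)

#' @rdname SuitabilityModel-class
#' @slot fit fitted backend object.
#' @export
setClass("GamSDM", contains = "SuitabilityModel",
  representation(fit = "ANY"))

#' @rdname SuitabilityModel-class
#' @export
setClass("GlmSDM", contains = "SuitabilityModel",
  representation(fit = "ANY"))

#' @rdname SuitabilityModel-class
#' @export
setClass("CartSDM", contains = "SuitabilityModel",
  representation(fit = "ANY"))

#' @rdname SuitabilityModel-class
#' @slot baseScore weighted training prevalence (the zero-tree prediction).
#' @slot nRounds number of boosting iterations retained.
#' @export
setClass("BrtSDM", contains = "SuitabilityModel",
  representation(fit = "ANY", baseScore = "numeric", nRounds = "integer"))

#' @rdname SuitabilityModel-class
#' @slot presenceValues presence-cell predictor values (rows = presences).
#' @export
setClass("BioclimSDM", contains = "SuitabilityModel",
  representation(presenceValues = "matrix"))

#' @rdname SuitabilityModel-class
#' @slot ranges per-variable value range of the training rows (Gower scaling).
#' @export
setClass("DomainSDM", contains = "SuitabilityModel",
  representation(presenceValues = "matrix", ranges = "numeric"))

#' @rdname SuitabilityModel-class
#' @slot center presence centroid.
#' @slot covInv inverse presence covariance.
#' @export
setClass("MahalSDM", contains = "SuitabilityModel",
  representation(center = "numeric", covInv = "matrix"))

#' @rdname SuitabilityModel-class
#' @slot coef fitted feature coefficients (linear + quadratic, standardized
#'   feature space).
#' @slot featureCenter,featureScale standardization of the feature columns.
#' @slot logSumExpEta log-sum-exp of the linear predictor over the training
#'   background (normalizer of the exponential model).
#' @slot entropy Shannon entropy of the fitted background distribution, used
#'   by the logistic output transform.
#' @export
setClass("MaxentSDM", contains = "SuitabilityModel",
  representation(coef = "numeric", featureCenter = "numeric",
    featureScale = "numeric", logSumExpEta = "numeric", entropy = "numeric"))

#' MapStack: aligned suitability maps from several models
#'
#' Holds two or more per-cell suitability maps sharing one grid geometry and
#' mask, for consensus and variance analysis. Members are typically the
#' model families of an ensemble, or one model refitted across assumed
#' prevalence levels.
#'
#' @slot grid the shared [EnvGrid] (geometry and mask reference).
#' @slot scores cells-by-members numeric matrix, `NA` on masked cells,
#'   values in `[0, 1]` on valid cells; column names are the member IDs.
#'
#' @seealso [mapStack()], [consensusMap()], [varianceMap()]
#' @export
setClass("MapStack",
  representation(grid = "EnvGrid", scores = "matrix")
)

setValidity("MapStack", function(object) {
  msg <- character()
  if (ncol(object@scores) < 2L) msg <- c(msg, "a MapStack needs >= 2 members")
  if (nrow(object@scores) != nCells(object@grid))
    msg <- c(msg, "scores must have one row per grid cell")
  if (is.null(colnames(object@scores)) || anyDuplicated(colnames(object@scores)))
    msg <- c(msg, "member ids must be unique column names")
  ok <- object@grid@mask
  if (nrow(object@scores) == nCells(object@grid)) {
    if (any(!is.na(object@scores[!ok, , drop = FALSE])))
      msg <- c(msg, "masked cells must be NA in every member")
    v <- object@scores[ok, , drop = FALSE]
    if (any(!is.finite(v)) || any(v < -1e-9) || any(v > 1 + 1e-9))
      msg <- c(msg, "member values must lie in [0, 1] on valid cells")
  }
  if (length(msg)) msg else TRUE
})

#' RangeChangeMap: four-class projection of range change
#'
#' Per-cell classification of the binarized current and future potential
#' ranges: `stable` (in range now and later), `contraction` (lost),
#' `expansion` (gained), `absent` (never in range). The classes partition
#' the valid cells.
#'
#' @slot grid the shared [EnvGrid].
#' @slot classes factor over all cells with the four levels above; `NA` on
#'   masked cells.
#'
#' @seealso [rangeChange()], [classCounts()]
#' @export
setClass("RangeChangeMap",
  representation(grid = "EnvGrid", classes = "factor")
)

setValidity("RangeChangeMap", function(object) {
  msg <- character()
  lv <- c("stable", "contraction", "expansion", "absent")
  if (!identical(levels(object@classes), lv))
    msg <- c(msg, "classes must have levels stable/contraction/expansion/absent")
  if (length(object@classes) != nCells(object@grid))
    msg <- c(msg, "classes must cover every grid cell")
  else {
    ok <- object@grid@mask
    if (any(is.na(object@classes[ok])))
      msg <- c(msg, "every valid cell must be classified")
    if (any(!is.na(object@classes[!ok])))
      msg <- c(msg, "masked cells must be NA")
  }
  if (length(msg)) msg else TRUE
})

#' EvalReport: repeated-split classification performance
#'
#' Per-repeat AUC, sensitivity, specificity and the threshold maximizing
#' sensitivity + specificity, from the 80/20 presence split protocol of
#' [cvEvaluate()], with mean and sample-SD summaries.
#'
#' @slot family model family evaluated.
#' @slot phi assumed prevalence used for fitting.
#' @slot repeats data.frame with one row per repeat (columns `repeat_`,
#'   `auc`, `sensitivity`, `specificity`, `threshold`).
#' @slot nRepeats number of repeats.
#'
#' @seealso [cvEvaluate()], [evalSummary()], [retainModels()]
#' @export
setClass("EvalReport",
  representation(family = "character", phi = "numeric",
    repeats = "data.frame", nRepeats = "integer")
)

setValidity("EvalReport", function(object) {
  msg <- character()
  need <- c("repeat_", "auc", "sensitivity", "specificity", "threshold")
  if (!all(need %in% names(object@repeats)))
    msg <- c(msg, paste("repeats must have columns:", paste(need, collapse = ", ")))
  else {
    v <- unlist(object@repeats[c("auc", "sensitivity", "specificity", "threshold")])
    if (any(v < -1e-9 | v > 1 + 1e-9))
      msg <- c(msg, "auc/sensitivity/specificity/threshold must lie in [0, 1]")
  }
  if (nrow(object@repeats) != object@nRepeats)
    msg <- c(msg, "nRepeats must match the number of rows")
  if (length(msg)) msg else TRUE
})

#' OMIResult: Outlying Mean Index niche analysis
#'
#' Output of [runOMI()]: the ordination of taxon marginality vectors against
#' a reference (background) environment, per-taxon niche position and
#' breadth along each axis, OMI statistics with one-tailed bootstrap
#' specialization p-values, and pairwise clade comparisons along the first
#' axis and the individual environmental gradients.
#'
#' @slot axes variables-by-axes matrix of unit-norm loadings.
#' @slot eigenvalues eigenvalues in decreasing order.
#' @slot varianceShare percentage of total marginality variation per axis
#'   (sums to 100).
#' @slot taxa taxon labels.
#' @slot weights count-proportional taxon weights used in the ordination.
#' @slot nichePosition taxa-by-axes matrix of mean axis scores.
#' @slot nicheBreadth taxa-by-axes matrix of axis-score SDs.
#' @slot omiStat squared marginality norm per taxon (standardized units).
#' @slot specializationP one-tailed bootstrap p-value per taxon.
#' @slot pairwiseAxis data.frame of one-sided Welch t-tests on axis scores.
#' @slot pairwiseVariables data.frame of one-sided Welch t-tests per
#'   environmental gradient.
#'
#' @seealso [runOMI()], [omiOrdination()], [specializationTest()]
#' @export
setClass("OMIResult",
  representation(axes = "matrix", eigenvalues = "numeric",
    varianceShare = "numeric", taxa = "character", weights = "numeric",
    nichePosition = "matrix", nicheBreadth = "matrix", omiStat = "numeric",
    specializationP = "numeric", pairwiseAxis = "data.frame",
    pairwiseVariables = "data.frame")
)

setValidity("OMIResult", function(object) {
  msg <- character()
  if (length(object@varianceShare) &&
      abs(sum(object@varianceShare) - 100) > 1e-6)
    msg <- c(msg, "varianceShare must sum to 100")
  if (any(object@nicheBreadth < 0)) msg <- c(msg, "niche breadth must be >= 0")
  nrm <- sqrt(colSums(object@axes^2))
  if (length(nrm) && any(abs(nrm - 1) > 1e-8))
    msg <- c(msg, "axis loadings must be unit-norm")
  if (length(msg)) msg else TRUE
})

#' VirtualSpeciesConfig: parameters of the simulated species
#'
#' Defines the logistic true-suitability surface of a virtual species on an
#' [EnvGrid]: `p(cell) = logistic(beta0 + sum(betaLinear * x) +
#' sum(betaQuadratic * x^2))` over the designated `trueVariables`
#' (standardized layers), plus the two-clade structure: clade 2's niche
#' optimum is shifted by `cladeOffset` SD units along `cladeGradient`, and
#' the clade presence counts mimic the strong size asymmetry of a recent
#' secondary invasion.
#'
#' @slot trueVariables layer names entering the true suitability.
#' @slot beta0 intercept.
#' @slot betaLinear,betaQuadratic coefficients per true variable.
#' @slot cladeOffset niche-optimum shift for clade 2, in SD units of the
#'   designated gradient.
#' @slot cladeGradient the temperature-like layer along which the clades
#'   differ.
#' @slot nPresence species-level presence count.
#' @slot cladeSizes presence counts for clade 1 and clade 2.
#' @slot decoyR target collinearity of the decoy layer with the first true
#'   variable.
#'
#' @seealso [virtualSpeciesConfig()], [trueSuitability()], [makeTwoClades()]
#' @export
setClass("VirtualSpeciesConfig",
  representation(trueVariables = "character", beta0 = "numeric",
    betaLinear = "numeric", betaQuadratic = "numeric",
    cladeOffset = "numeric", cladeGradient = "character",
    nPresence = "integer", cladeSizes = "integer", decoyR = "numeric")
)

setValidity("VirtualSpeciesConfig", function(object) {
  msg <- character()
  k <- length(object@trueVariables)
  if (length(object@betaLinear) != k || length(object@betaQuadratic) != k)
    msg <- c(msg, "betaLinear and betaQuadratic must match trueVariables")
  if (object@decoyR <= 0 || object@decoyR >= 1)
    msg <- c(msg, "decoyR must lie in (0, 1)")
  if (object@nPresence < 1L) msg <- c(msg, "nPresence must be >= 1")
  if (length(object@cladeSizes) != 2L || any(object@cladeSizes < 1L))
    msg <- c(msg, "cladeSizes must be two positive counts")
  if (!(object@cladeGradient %in% object@trueVariables))
    msg <- c(msg, "cladeGradient must be one of trueVariables")
  if (length(msg)) msg else TRUE
})
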