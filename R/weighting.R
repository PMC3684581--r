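#' Prevalence class weights
#'
#' Per-row weights making the class *totals* proportional to the assumed
#' prevalence: presence rows get `phi / nPresence`, background rows
#' `(1 - phi) / nBackground`, so the summed presence weight over the summed
#' background weight is `phi / (1 - phi)` and all weights sum to 1. At
#' `phi = 0.5` the two classes weigh the same; at `phi = 0.9` the presence
#' class weighs 9 times the background class.
#'
#' @param nPresence,nBackground row counts per class (>= 1).
#' @param phi assumed species prevalence in (0, 1).
#' @return named numeric `c(presence = , background = )` per-row weights.
#' @seealso [buildTrainingTable()]
#' @export
classWeights <- function(nPresence, nBackground, phi) {
  if (!is.numeric(phi) || length(phi) != 1L || phi <= 0 || phi >= 1)
    stop("phi must lie strictly in (0, 1)")
  stopifnot(nPresence >= 1, nBackground >= 1)
  c(presence = phi / nPresence, background = (1 - phi) / nBackground)
}

#' Effective prevalence of an unweighted presence/background table
#'
#' The prevalence implicitly assumed when presence and background rows
#' weigh equally. Computed as `nPresence / nBackground`, which at
#' background sizes that dwarf the presences is numerically
#' indistinguishable from the proportion `nPresence / (nPresence +
#' nBackground)` (380 presences against 100,000 background cells give
#' 0.0038 either way at one significant digit).
#'
#' @param nPresence,nBackground row counts.
#' @return the ratio `nPresence / nBackground`.
#' @export
effectivePrevalence <- function(nPresence, nBackground) {
  stopifnot(nBackground >= 1, nPresence >= 0)
  nPresence / nBackground
}

#' Assemble a presence/background training table
#'
#' Rows are the presence cells (label 1) followed by the background cells
#' (label 0); the `weight` column carries the prevalence class weights
#' rescaled so that all weights sum to the row count (weighted fits are
#' scale-invariant, but AIC is not, so one scale convention is fixed
#' here). A cell sampled both as presence and as background contributes
#' one row per role — background data are available environment, not
#' absences.
#'
#' @param grid an [EnvGrid].
#' @param presences a [PresenceSet] (or integer cell IDs).
#' @param background integer vector of background cell IDs.
#' @param phi assumed prevalence.
#' @param variables predictor layers to include (default: all).
#' @return data.frame with columns `cell`, `label`, `weight`, then one
#'   column per predictor; attribute `"phi"` records the prevalence.
#' @export
buildTrainingTable <- function(grid, presences, background, phi = 0.5,
                               variables = layerNames(grid)) {
  pc <- if (methods::is(presences, "PresenceSet")) presenceCells(presences)
        else sort(unique(as.integer(presences)))
  bc <- as.integer(background)
  stopifnot(length(pc) >= 1L, length(bc) >= 1L)
  if (any(!grid@mask[c(pc, bc)]))
    stop("training cells must all be valid grid cells")
  w <- classWeights(length(pc), length(bc), phi)
  n <- length(pc) + length(bc)
  tab <- data.frame(
    cell = c(pc, bc),
    label = rep(c(1L, 0L), c(length(pc), length(bc))),
    weight = rep(w, c(length(pc), length(bc))) * n
  )
  tab <- cbind(tab, as.data.frame(grid@layers[tab$cell, variables,
                                              drop = FALSE]))
  attr(tab, "phi") <- phi
  tab
}

.predictorNames <- function(table)
  setdiff(names(table), c("cell", "label", "weight"))

## One weighted binomial fit of `vars` (possibly empty -> intercept only).
.fitStep <- function(table, vars, fitFamily) {
  rhs <- if (!length(vars)) "1"
         else if (fitFamily == "gam")
           paste(sprintf("s(%s, k = 3)", vars), collapse = " + ")
         else
           paste(sprintf("%s + I(%s^2)", vars, vars), collapse = " + ")
  fml <- stats::as.formula(paste("label ~", rhs))
  dat <- table
  dat$.w <- table$weight
  suppressWarnings(
    if (fitFamily == "gam")
      mgcv::gam(fml, family = stats::binomial(), data = dat, weights = .w,
                method = "REML")
    else
      stats::glm(fml, family = stats::binomial(), data = dat, weights = .w)
  )
}

#' Forward variable selection with a collinearity filter
#'
#' Greedy forward selection for a weighted binomial model (GAM with k = 3
#' smooths by default, or a quadratic GLM). Step 1 retains the single
#' predictor with the highest explained deviance; before every later step,
#' candidates with `|Pearson r| >= rMax` against any already-selected
#' predictor are removed from the pool (correlations computed over the
#' training rows, unweighted). Addition stops when the new term is not
#' significant (chi-square test on the weighted deviance drop, with the
#' term's added coefficients as degrees of freedom) or when AIC does not
#' decrease. Exact ties in deviance resolve to the candidate listed first.
#'
#' @param table a training table from [buildTrainingTable()].
#' @param candidates predictor names to consider (default: all predictor
#'   columns).
#' @param rMax collinearity cut-off (Pearson, absolute).
#' @param alpha significance level for the deviance-difference test.
#' @param fitFamily `"gam"` (k = 3 smooths) or `"glm"` (linear +
#'   quadratic).
#' @return list with `selected` (ordered character vector, possibly
#'   empty) and `trace` (data.frame: step, variable, deviance, aic,
#'   pValue, accepted, removed).
#' @export
forwardSelect <- function(table, candidates = .predictorNames(table),
                          rMax = 0.8, alpha = 0.05,
                          fitFamily = c("gam", "glm")) {
  fitFamily <- match.arg(fitFamily)
  stopifnot(length(candidates) >= 1L,
            all(candidates %in% .predictorNames(table)))
  selected <- character()
  trace <- data.frame(step = integer(), variable = character(),
                      deviance = numeric(), aic = numeric(),
                      pValue = numeric(), accepted = logical(),
                      removed = character(), stringsAsFactors = FALSE)
  current <- .fitStep(table, character(), fitFamily)
  pool <- candidates
  step <- 0L
  repeat {
    step <- step + 1L
    removed <- character()
    if (length(selected)) {
      keep <- vapply(pool, function(v)
        all(abs(stats::cor(table[[v]], table[, selected, drop = FALSE])) < rMax),
        TRUE)
      removed <- pool[!keep]
      pool <- pool[keep]
    }
    if (!length(pool)) break
    fits <- lapply(pool, function(v)
      .fitStep(table, c(selected, v), fitFamily))
    dev <- vapply(fits, stats::deviance, 0)
    best <- which.min(dev)  # first index wins exact ties
    cand <- pool[best]
    fit <- fits[[best]]
    dDev <- stats::deviance(current) - dev[best]
    dDf <- length(stats::coef(fit)) - length(stats::coef(current))
    p <- stats::pchisq(max(dDev, 0), df = max(dDf, 1), lower.tail = FALSE)
    aicNew <- stats::AIC(fit)
    aicOld <- stats::AIC(current)
    accepted <- p <= alpha && aicNew < aicOld
    trace <- rbind(trace, data.frame(
      step = step, variable = cand, deviance = dev[best], aic = aicNew,
      pValue = p, accepted = accepted,
      removed = paste(removed, collapse = ";"), stringsAsFactors = FALSE))
    if (!accepted) break
    selected <- c(selected, cand)
    pool <- setdiff(pool, cand)
    current <- fit
    if (!length(pool)) break
  }
  list(selected = selected, trace = trace)
}

#' Write a forward-selection trace as CSV
#'
#' @param selection result of [forwardSelect()].
#' @param path output CSV path.
#' @export
writeSelectionTrace <- function(selection, path) {
  utils::write.csv(selection$trace, path, row.names = FALSE)
  invisible(path)
}
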