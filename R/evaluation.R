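#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' `P(score_presence > score_absence) + 0.5 P(tie)`, computed via midranks,
#' identical to exhaustive pair counting.
#'
#' @param scoresPresence,scoresAbsence numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(scoresPresence, scoresAbsence) {
  np <- length(scoresPresence); na <- length(scoresAbsence)
  stopifnot(np >= 1, na >= 1)
  r <- rank(c(scoresPresence, scoresAbsence))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' Threshold maximizing sensitivity + specificity (MST)
#'
#' Exhaustive scan over the midpoints of consecutive sorted unique scores,
#' plus 0 and 1. A cell with score `>= threshold` is predicted present.
#' Ties in the objective resolve to the lowest threshold.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 labels (both classes must occur).
#' @return named numeric `c(threshold, sensitivity, specificity)`.
#' @export
mstThreshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both labels must be present; sensitivity or specificity is undefined otherwise")
  u <- sort(unique(scores))
  mids <- if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2 else numeric()
  cands <- sort(unique(c(0, mids, 1)))
  sp <- scores[labels == 1L]; sa <- scores[labels == 0L]
  sens <- vapply(cands, function(t) mean(sp >= t), 0)
  spec <- vapply(cands, function(t) mean(sa < t), 0)
  best <- which.max(sens + spec)  # first = lowest threshold on ties
  c(threshold = cands[best], sensitivity = sens[best],
    specificity = spec[best])
}

#' Repeated-split evaluation of a model family
#'
#' The repeated 80/20 protocol: per repeat, the presence cells are split
#' 80/20; the model is fitted on the training presences plus an
#' equally-sized random pseudo-absence sample, and tested on the held-out
#' presences plus a disjoint pseudo-absence sample of their size. AUC and
#' the MST threshold (with its sensitivity and specificity) are computed
#' on the test scores; the summary is the mean and sample SD across
#' repeats. Pseudo-absences are random valid cells excluding all presence
#' cells, so the test labels are coherent.
#'
#' @param presences a [PresenceSet] (>= 10 cells).
#' @param grid an [EnvGrid].
#' @param family model family label for [fitModel()], or a function
#'   `function(table) -> SuitabilityModel`.
#' @param variables predictors used for fitting.
#' @param phi assumed prevalence for the training weights.
#' @param nRepeats number of random splits.
#' @param trainFrac fraction of presences used for fitting.
#' @param seed integer seed; the whole report is reproducible under it.
#' @param ... passed to [fitModel()].
#' @return an [EvalReport].
#' @export
cvEvaluate <- function(presences, grid, family = "GAM",
                       variables = layerNames(grid), phi = 0.5,
                       nRepeats = 10, trainFrac = 0.8, seed = 1, ...) {
  pc <- presenceCells(presences)
  if (length(pc) < 10L) stop("need at least 10 presence cells")
  fitFun <- if (is.function(family)) family
            else function(tab) fitModel(tab, family, variables, ...)
  famLabel <- if (is.function(family)) "custom" else toupper(family)
  pool <- setdiff(validCells(grid), pc)
  rows <- lapply(seq_len(nRepeats), function(r) {
    withr::with_seed(as.integer(seed) + r, {
      idx <- sample(length(pc))
      nTrain <- round(trainFrac * length(pc))
      trP <- pc[idx[seq_len(nTrain)]]
      teP <- pc[idx[-seq_len(nTrain)]]
      paTrain <- sample(pool, length(trP))
      paTest <- sample(setdiff(pool, paTrain), length(teP))
      tab <- buildTrainingTable(grid, trP, paTrain, phi = phi,
                                variables = variables)
      map <- predictMap(fitFun(tab), grid)
      scores <- c(map[teP], map[paTest])
      labels <- rep(c(1L, 0L), c(length(teP), length(paTest)))
      m <- mstThreshold(scores, labels)
      data.frame(repeat_ = r, auc = aucScore(map[teP], map[paTest]),
                 sensitivity = m[["sensitivity"]],
                 specificity = m[["specificity"]],
                 threshold = m[["threshold"]])
    })
  })
  new("EvalReport", family = famLabel, phi = phi,
      repeats = do.call(rbind, rows), nRepeats = as.integer(nRepeats))
}

#' Retain model families by mean AUC
#'
#' Keeps the families whose mean AUC is at or above the cut-off (the bound
#' is inclusive: a family at exactly 0.9 is retained). With no family
#' above the cut-off, a warning is raised and the single best family is
#' returned as a fallback.
#'
#' @param reports a named numeric vector of mean AUCs, or a list of
#'   [EvalReport]s (names taken from their family labels).
#' @param aucMin retention cut-off.
#' @return character vector of retained family labels.
#' @export
retainModels <- function(reports, aucMin = 0.9) {
  if (is.list(reports)) {
    auc <- vapply(reports, function(r) mean(r@repeats$auc), 0)
    names(auc) <- vapply(reports, function(r) r@family, "")
  } else auc <- reports
  kept <- names(auc)[auc >= aucMin]
  if (!length(kept)) {
    warning("no family reaches AUC >= ", aucMin,
            "; falling back to the best single model (",
            names(auc)[which.max(auc)], ")")
    kept <- names(auc)[which.max(auc)]
  }
  kept
}

#' Write evaluation reports as a performance table CSV
#'
#' One row per report, columns `model`, `prevalence`, and `mean+/-sd` for
#' AUC, sensitivity and specificity — the layout of a model-performance
#' table.
#'
#' @param reports list of [EvalReport]s.
#' @param path output CSV path.
#' @export
writeEvalCSV <- function(reports, path) {
  fmt <- function(m, s) sprintf("%.3f±%.3f", m, s)
  rows <- lapply(reports, function(r) {
    s <- evalSummary(r)
    g <- function(k) fmt(s$mean[s$metric == k], s$sd[s$metric == k])
    data.frame(model = r@family, prevalence = r@phi, AUC = g("auc"),
               Sensitivity = g("sensitivity"), Specificity = g("specificity"),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
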