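## The eight suitability-model families behind one interface: fit on a
## weighted presence/background training table, predict in [0, 1] per cell.

.tableXY <- function(table, variables = .predictorNames(table)) {
  list(x = as.matrix(table[, variables, drop = FALSE]),
       y = table$label, w = table$weight, variables = variables)
}

.presenceValues <- function(table, variables = .predictorNames(table)) {
  as.matrix(table[table$label == 1L, variables, drop = FALSE])
}

.checkTwoClasses <- function(table, min = 1L) {
  if (sum(table$label == 1L) < min || sum(table$label == 0L) < min)
    stop("training table needs at least ", min, " rows of each label")
}

#' Linear rescaling to the unit interval
#'
#' `v <- (v - min) / (max - min)` over the finite entries, so the minimum
#' maps to 0 and the maximum to 1 exactly. Used to make raw Mahalanobis
#' scores (`1 - D^2`, unbounded below) comparable to the probability-scale
#' outputs of the other families.
#'
#' @param values numeric vector (`NA` passed through).
#' @return rescaled vector on `[0, 1]`.
#' @export
rescaleUnit <- function(values) {
  r <- range(values, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] <= r[1])
    stop("rescaleUnit is undefined for constant input")
  (values - r[1]) / (r[2] - r[1])
}

## ---- weighted regression families -----------------------------------------

#' Fit a weighted binomial GAM with curvature-limited smooths
#'
#' One smooth per predictor with basis dimension k = 3, i.e. model
#' complexity capped at quadratic-like curvature, fitted by `mgcv::gam`
#' with the table's prevalence weights.
#'
#' @param table training table from [buildTrainingTable()].
#' @param variables predictors (default: all predictor columns).
#' @return a `GamSDM` [SuitabilityModel].
#' @export
fitGamK3 <- function(table, variables = .predictorNames(table)) {
  .checkTwoClasses(table, 10L)
  fit <- .fitStep(table[, c("label", "weight", variables)], variables, "gam")
  if (!fit$converged)
    stop("GAM did not converge on variables: ",
         paste(variables, collapse = ", "))
  new("GamSDM", family = "GAM", variables = variables,
      supportsWeights = TRUE, fit = fit)
}

#' Fit a weighted binomial GLM with linear + quadratic terms
#'
#' @inheritParams fitGamK3
#' @return a `GlmSDM` [SuitabilityModel].
#' @export
fitGlmQuadratic <- function(table, variables = .predictorNames(table)) {
  .checkTwoClasses(table, 10L)
  fit <- .fitStep(table[, c("label", "weight", variables)], variables, "glm")
  if (!fit$converged)
    stop("GLM did not converge on variables: ",
         paste(variables, collapse = ", "))
  new("GlmSDM", family = "GLM", variables = variables,
      supportsWeights = TRUE, fit = fit)
}

#' Fit a weighted classification tree (CART)
#'
#' Single `rpart` classification tree on linear predictor terms, with
#' cost-complexity pruning chosen by the tree's internal cross-validation
#' (1-SE rule: the smallest tree whose CV error is within one SE of the
#' minimum). Leaf predictions are weighted presence proportions. The
#' internal CV uses the current RNG stream.
#'
#' @inheritParams fitGamK3
#' @param xval internal cross-validation folds.
#' @param cp initial complexity parameter passed to `rpart`.
#' @return a `CartSDM` [SuitabilityModel].
#' @export
fitCart <- function(table, variables = .predictorNames(table),
                    xval = 10, cp = 0.001) {
  .checkTwoClasses(table)
  dat <- table[, variables, drop = FALSE]
  dat$.y <- factor(table$label, levels = c(0L, 1L))
  dat$.w <- table$weight
  fml <- stats::as.formula(paste(".y ~", paste(variables, collapse = " + ")))
  fit <- rpart::rpart(fml, data = dat, weights = .w, method = "class",
                      control = rpart::rpart.control(cp = cp, xval = xval))
  ct <- fit$cptable
  if (nrow(ct) > 1L && "xerror" %in% colnames(ct)) {
    thr <- min(ct[, "xerror"]) + ct[which.min(ct[, "xerror"]), "xstd"]
    cpPick <- ct[which(ct[, "xerror"] <= thr)[1], "CP"]
    fit <- rpart::prune(fit, cp = cpPick)
  }
  new("CartSDM", family = "CART", variables = variables,
      supportsWeights = TRUE, fit = fit)
}

#' Fit boosted regression trees (BRT)
#'
#' Stagewise stochastic gradient boosting of shallow regression trees on
#' the Bernoulli deviance with case weights (via `xgboost`). The tree
#' count is chosen by held-out deviance: stratified k-fold
#' cross-validation with early stopping picks the iteration minimizing
#' held-out log-loss, and the model is then fitted on all rows with that
#' tree count — the standard stepwise-BRT recipe, with its usual bag
#' fraction of one half.
#'
#' @inheritParams fitGamK3
#' @param learningRate shrinkage per tree.
#' @param depth maximum tree depth.
#' @param nRoundsMax upper bound on boosting iterations (0 gives the
#'   constant weighted-prevalence model).
#' @param bagFraction row subsample fraction per tree.
#' @param nFold folds for tree-count selection.
#' @param earlyStop early-stopping patience (rounds).
#' @return a `BrtSDM` [SuitabilityModel].
#' @export
fitBrt <- function(table, variables = .predictorNames(table),
                   learningRate = 0.01, depth = 3, nRoundsMax = 1500,
                   bagFraction = 0.5, nFold = 5, earlyStop = 30) {
  .checkTwoClasses(table)
  d <- .tableXY(table, variables)
  p0 <- sum(d$w * d$y) / sum(d$w)
  if (nRoundsMax == 0)
    return(new("BrtSDM", family = "BRT", variables = variables,
               supportsWeights = TRUE, fit = NULL, baseScore = p0,
               nRounds = 0L))
  params <- list(objective = "binary:logistic", eta = learningRate,
                 max_depth = depth, nthread = 1, base_score = p0,
                 subsample = bagFraction, colsample_bytree = 1, seed = 99)
  dall <- xgboost::xgb.DMatrix(d$x, label = d$y, weight = d$w, nthread = 1)
  cv <- xgboost::xgb.cv(params = params, data = dall, nrounds = nRoundsMax,
                        nfold = nFold, stratified = TRUE,
                        early_stopping_rounds = earlyStop, verbose = 0)
  best <- cv$early_stop$best_iteration
  best <- max(1L, as.integer(if (is.null(best)) nRoundsMax else best))
  fit <- xgboost::xgb.train(params = params, data = dall, nrounds = best,
                            verbose = 0)
  new("BrtSDM", family = "BRT", variables = variables,
      supportsWeights = TRUE, fit = fit, baseScore = p0, nRounds = best)
}

## ---- presence-only families ------------------------------------------------
## These ignore the prevalence weights: background data cannot be weighted
## into them, so they see the presence sample only (DOMAIN's Gower ranges
## and the exponential model's reference distribution use the table rows).

## Midrank empirical CDF: F(x) = (#{xi < x} + 0.5 #{xi = x}) / n.
## Exactly 0.5 at the sample median, 0 below the minimum, 1 above the
## maximum.
.midrankCdf <- function(sample, x) {
  (vapply(x, function(v) sum(sample < v) + 0.5 * sum(sample == v), 0)) /
    length(sample)
}

#' Fit a BIOCLIM percentile-envelope model
#'
#' Classic climatic-envelope scoring: per variable, the score is
#' `1 - 2 * |F(x) - 0.5|` where `F` is the presence sample's (midrank)
#' empirical CDF, so a cell at the presence median of a variable scores 1
#' and a cell outside the presence range scores 0. The cell score is the
#' minimum over variables.
#'
#' @inheritParams fitGamK3
#' @return a `BioclimSDM` [SuitabilityModel].
#' @export
fitBioclim <- function(table, variables = .predictorNames(table)) {
  pv <- .presenceValues(table, variables)
  if (nrow(pv) < 2L) stop("BIOCLIM needs at least 2 presence rows")
  new("BioclimSDM", family = "BIOCLIM", variables = variables,
      supportsWeights = FALSE, presenceValues = pv)
}

#' Fit a DOMAIN (Gower similarity) model
#'
#' Score of a cell = Gower similarity to its most similar presence:
#' `1 - mean_v |x_cv - x_pv| / range_v`, ranges taken over the training
#' rows, maximized over presences and clamped to `[0, 1]`.
#'
#' @inheritParams fitGamK3
#' @return a `DomainSDM` [SuitabilityModel].
#' @export
fitDomain <- function(table, variables = .predictorNames(table)) {
  pv <- .presenceValues(table, variables)
  if (nrow(pv) < 1L) stop("DOMAIN needs at least 1 presence row")
  rng <- apply(as.matrix(table[, variables, drop = FALSE]), 2,
               function(v) diff(range(v)))
  if (any(rng <= 0))
    stop("degenerate (constant) variables for DOMAIN: ",
         paste(variables[rng <= 0], collapse = ", "))
  new("DomainSDM", family = "DOMAIN", variables = variables,
      supportsWeights = FALSE, presenceValues = pv, ranges = rng)
}

#' Fit a Mahalanobis-distance model
#'
#' Raw score `1 - D^2(cell; presence mean, presence covariance)`: 1 at the
#' presence centroid (the maximum), unboundedly negative far away. The raw
#' score is stored; [predictMap()] rescales it linearly over the valid
#' cells of the prediction grid so each map spans `[0, 1]`.
#'
#' @inheritParams fitGamK3
#' @return a `MahalSDM` [SuitabilityModel].
#' @export
fitMahalanobis <- function(table, variables = .predictorNames(table)) {
  pv <- .presenceValues(table, variables)
  if (nrow(pv) <= length(variables))
    stop("MAHAL needs more presences than variables")
  cv <- stats::cov(pv)
  covInv <- tryCatch(solve(cv), error = function(e)
    stop("singular presence covariance; remove degenerate (constant or ",
         "perfectly collinear) variables", call. = FALSE))
  new("MahalSDM", family = "MAHAL", variables = variables,
      supportsWeights = FALSE, center = colMeans(pv), covInv = covInv)
}

## ---- MAXENT-like exponential model -----------------------------------------

.maxentFeatures <- function(x) cbind(x, x^2)

## Penalized presence/background exponential model fitted by proximal
## gradient (ISTA with backtracking) on the convex objective
##   -mean_presence(eta) + logsumexp_background(eta) + sum(penalty * |coef|).
.fitMaxentCore <- function(fp, fb, penalty, maxIter = 500, tol = 1e-8) {
  k <- ncol(fp)
  beta <- numeric(k)
  meanP <- colMeans(fp)
  obj <- function(b) {
    eb <- fb %*% b
    m <- max(eb)
    -sum(meanP * b) + m + log(mean(exp(eb - m))) + sum(penalty * abs(b))
  }
  smoothGrad <- function(b) {
    eb <- drop(fb %*% b)
    q <- exp(eb - max(eb)); q <- q / sum(q)
    -meanP + colSums(fb * q)
  }
  step <- 1
  fOld <- obj(beta)
  for (it in seq_len(maxIter)) {
    g <- smoothGrad(beta)
    repeat {
      cand <- beta - step * g
      cand <- sign(cand) * pmax(abs(cand) - step * penalty, 0)  # soft threshold
      fNew <- obj(cand)
      if (is.finite(fNew) && fNew <= fOld + 1e-12) break
      step <- step / 2
      if (step < 1e-12) { cand <- beta; fNew <- fOld; break }
    }
    moved <- sqrt(sum((cand - beta)^2))
    beta <- cand
    if (fOld - fNew < tol && moved < 1e-8) break
    fOld <- fNew
    step <- min(step * 1.5, 10)
  }
  beta
}

#' Fit a regularized presence/background exponential model
#'
#' A maximum-entropy style suitability model: linear + quadratic features
#' (standardized over the background rows), coefficients fitted by
#' maximizing the L1-penalized presence log-likelihood against the
#' background distribution, and a logistic output transform
#' `p = e^H q / (1 + e^H q)` (tau = 0.5), where `q` is the cell's density
#' under the fitted exponential model relative to the training background
#' and `H` its background entropy — so a model indistinguishable from the
#' background scores 0.5 everywhere. This is a self-contained realization
#' of the presence/background exponential-model idea, not a port of any
#' particular program.
#'
#' @inheritParams fitGamK3
#' @param penalty L1 penalty per standardized feature; default
#'   `1 / sqrt(nPresence)`.
#' @return a `MaxentSDM` [SuitabilityModel].
#' @export
fitMaxentLike <- function(table, variables = .predictorNames(table),
                          penalty = NULL) {
  pv <- .presenceValues(table, variables)
  bv <- as.matrix(table[table$label == 0L, variables, drop = FALSE])
  if (nrow(pv) < 2L || nrow(bv) < 2L)
    stop("needs at least 2 presence and 2 background rows")
  if (is.null(penalty)) penalty <- 1 / sqrt(nrow(pv))
  fb <- .maxentFeatures(bv)
  ctr <- colMeans(fb)
  scl <- apply(fb, 2, stats::sd)
  scl[scl == 0] <- 1
  fbz <- sweep(sweep(fb, 2, ctr), 2, scl, "/")
  fpz <- sweep(sweep(.maxentFeatures(pv), 2, ctr), 2, scl, "/")
  beta <- .fitMaxentCore(fpz, fbz, penalty = rep(penalty, ncol(fbz)))
  eb <- drop(fbz %*% beta)
  m <- max(eb)
  logSum <- m + log(sum(exp(eb - m)))
  q <- exp(eb - logSum)
  entropy <- -sum(q * log(pmax(q, 1e-300)))
  new("MaxentSDM", family = "MAXENT", variables = variables,
      supportsWeights = FALSE, coef = beta, featureCenter = ctr,
      featureScale = scl, logSumExpEta = logSum, entropy = entropy)
}

## ---- dispatcher -------------------------------------------------------------

#' Fit any of the eight model families
#'
#' Single entry point used by the evaluation and pipeline stages.
#' Weighted families (GAM, GLM, CART, BRT) use the table's prevalence
#' weights; presence-only families (BIOCLIM, DOMAIN, MAHAL, MAXENT) ignore
#' them.
#'
#' @param table training table from [buildTrainingTable()].
#' @param family one of `"GAM"`, `"GLM"`, `"CART"`, `"BRT"`, `"BIOCLIM"`,
#'   `"DOMAIN"`, `"MAHAL"`, `"MAXENT"`.
#' @param variables predictors (default: all predictor columns).
#' @param ... family-specific options passed through.
#' @return a [SuitabilityModel].
#' @export
fitModel <- function(table, family, variables = .predictorNames(table), ...) {
  switch(toupper(family),
    GAM = fitGamK3(table, variables),
    GLM = fitGlmQuadratic(table, variables),
    CART = fitCart(table, variables, ...),
    BRT = fitBrt(table, variables, ...),
    BIOCLIM = fitBioclim(table, variables),
    DOMAIN = fitDomain(table, variables),
    MAHAL = fitMahalanobis(table, variables),
    MAXENT = fitMaxentLike(table, variables, ...),
    stop("unknown model family: ", family))
}

#' The eight supported model family labels
#' @export
sdmFamilies <- function() {
  c("GAM", "GLM", "CART", "BRT", "BIOCLIM", "DOMAIN", "MAHAL", "MAXENT")
}

## ---- prediction -------------------------------------------------------------

.gridNewdata <- function(grid, variables) {
  miss <- setdiff(variables, layerNames(grid))
  if (length(miss))
    stop("grid lacks model variables: ", paste(miss, collapse = ", "))
  nd <- as.data.frame(grid@layers[grid@mask, variables, drop = FALSE])
  if (!length(variables)) nd$.const <- rep(1, sum(grid@mask))
  nd
}

.emitMap <- function(grid, valid) {
  out <- rep(NA_real_, nCells(grid))
  out[grid@mask] <- pmin(pmax(valid, 0), 1)
  out
}

#' @rdname predictMap
#' @export
setMethod("predictMap", signature("GamSDM", "EnvGrid"), function(model, grid) {
  nd <- .gridNewdata(grid, model@variables)
  .emitMap(grid, as.numeric(mgcv::predict.gam(model@fit, newdata = nd,
                                              type = "response")))
})

#' @rdname predictMap
#' @export
setMethod("predictMap", signature("GlmSDM", "EnvGrid"), function(model, grid) {
  nd <- .gridNewdata(grid, model@variables)
  .emitMap(grid, as.numeric(stats::predict(model@fit, newdata = nd,
                                           type = "response")))
})

#' @rdname predictMap
#' @export
setMethod("predictMap", signature("CartSDM", "EnvGrid"), function(model, grid) {
  nd <- .gridNewdata(grid, model@variables)
  pr <- stats::predict(model@fit, newdata = nd, type = "prob")
  .emitMap(grid, as.numeric(pr[, "1"]))
})

#' @rdname predictMap
#' @export
setMethod("predictMap", signature("BrtSDM", "EnvGrid"), function(model, grid) {
  nd <- as.matrix(.gridNewdata(grid, model@variables))
  if (model@nRounds == 0L)
    return(.emitMap(grid, rep(model@baseScore, nrow(nd))))
  dm <- xgboost::xgb.DMatrix(nd, nthread = 1)
  .emitMap(grid, as.numeric(stats::predict(model@fit, dm)))
})

#' @rdname predictMap
#' @export
setMethod("predictMap", signature("BioclimSDM", "EnvGrid"),
          function(model, grid) {
  nd <- as.matrix(.gridNewdata(grid, model@variables))
  pv <- model@presenceValues
  score <- rep(1, nrow(nd))
  for (j in seq_along(model@variables)) {
    f <- .midrankCdf(pv[, j], nd[, j])
    s <- 1 - 2 * abs(f - 0.5)
    s[nd[, j] < min(pv[, j]) | nd[, j] > max(pv[, j])] <- 0
    score <- pmin(score, s)
  }
  .emitMap(grid, score)
})

#' @rdname predictMap
#' @export
setMethod("predictMap", signature("DomainSDM", "EnvGrid"),
          function(model, grid) {
  nd <- as.matrix(.gridNewdata(grid, model@variables))
  pv <- model@presenceValues
  V <- length(model@variables)
  best <- rep(-Inf, nrow(nd))
  for (p in seq_len(nrow(pv))) {
    dist <- rowSums(sweep(abs(sweep(nd, 2, pv[p, ])), 2, model@ranges, "/"))
    best <- pmax(best, 1 - dist / V)
  }
  .emitMap(grid, pmin(pmax(best, 0), 1))
})

#' @rdname predictMap
#' @export
setMethod("predictMap", signature("MahalSDM", "EnvGrid"),
          function(model, grid) {
  nd <- as.matrix(.gridNewdata(grid, model@variables))
  d2 <- stats::mahalanobis(nd, model@center, model@covInv, inverted = TRUE)
  .emitMap(grid, rescaleUnit(1 - d2))
})

#' Raw (unrescaled) Mahalanobis suitability scores
#'
#' `1 - D^2` per valid cell, the scale on which the presence centroid
#' scores exactly 1. [predictMap()] applies [rescaleUnit()] to this.
#'
#' @param model a `MahalSDM`.
#' @param grid an [EnvGrid].
#' @return numeric per-cell vector, `NA` on masked cells.
#' @export
mahalRawScores <- function(model, grid) {
  stopifnot(methods::is(model, "MahalSDM"))
  nd <- as.matrix(.gridNewdata(grid, model@variables))
  out <- rep(NA_real_, nCells(grid))
  out[grid@mask] <- 1 - stats::mahalanobis(nd, model@center, model@covInv,
                                           inverted = TRUE)
  out
}

#' @rdname predictMap
#' @export
setMethod("predictMap", signature("MaxentSDM", "EnvGrid"),
          function(model, grid) {
  nd <- as.matrix(.gridNewdata(grid, model@variables))
  fz <- sweep(sweep(.maxentFeatures(nd), 2, model@featureCenter), 2,
              model@featureScale, "/")
  eta <- drop(fz %*% model@coef)
  logq <- eta - model@logSumExpEta
  .emitMap(grid, stats::plogis(logq + model@entropy))
})
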