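#' Virtual species configuration
#'
#' Builds a [VirtualSpeciesConfig]. The defaults define a species with a
#' strong unimodal (quadratic-logistic) niche on two standardized
#' environmental gradients, a 288/73 clade size asymmetry, and a clade-2
#' optimum shifted 1.5 SD along the temperature-like first gradient —
#' the structure the downstream prevalence / family / clade analyses
#' assume.
#'
#' The default coefficients are the vertex form `eta = 2.2 - 0.3 * (x1 -
#' 4)^2 - 0.3 * (x2 - 4)^2` expanded: a broad unimodal niche whose optimum
#' sits beyond the warm/wet edge of the realized environment, so
#' suitability rises monotonically toward that edge across most of the
#' grid, suitable habitat is scarce, and presence/background separability
#' is strong (AUC of the true surface about 0.92-0.95) while suitability
#' still varies learnably over the bulk of cells.
#'
#' @param trueVariables layers entering the true suitability.
#' @param beta0 intercept of the logistic surface.
#' @param betaLinear,betaQuadratic per-variable coefficients.
#' @param cladeOffset clade-2 optimum shift in SD units along
#'   `cladeGradient`.
#' @param cladeGradient layer along which the clades differentiate.
#' @param nPresence species-level presence count.
#' @param cladeSizes clade 1 / clade 2 presence counts.
#' @param decoyR target collinearity of the decoy layer with the first
#'   true variable.
#' @return a [VirtualSpeciesConfig].
#' @export
virtualSpeciesConfig <- function(trueVariables = c("env1", "env2"),
                                 beta0 = -7.4,
                                 betaLinear = c(2.4, 2.4),
                                 betaQuadratic = c(-0.3, -0.3),
                                 cladeOffset = 1.5,
                                 cladeGradient = trueVariables[1],
                                 nPresence = 380,
                                 cladeSizes = c(288, 73),
                                 decoyR = 0.9) {
  new("VirtualSpeciesConfig", trueVariables = trueVariables,
      beta0 = beta0, betaLinear = betaLinear, betaQuadratic = betaQuadratic,
      cladeOffset = cladeOffset, cladeGradient = cladeGradient,
      nPresence = as.integer(nPresence), cladeSizes = as.integer(cladeSizes),
      decoyR = decoyR)
}

## Smooth random field: superposition of low-frequency cosine waves.
## Gives spatially autocorrelated layers, which is what makes environmental
## collinearity and spatially clustered presences realistic.
.smoothField <- function(nRows, nCols, nWaves = 60, maxFreq = 10) {
  co <- (col(matrix(0, nRows, nCols)) - 0.5) / nCols
  ro <- (row(matrix(0, nRows, nCols)) - 0.5) / nRows
  f <- matrix(0, nRows, nCols)
  for (k in seq_len(nWaves)) {
    fx <- stats::runif(1, -maxFreq, maxFreq)
    fy <- stats::runif(1, -maxFreq, maxFreq)
    ph <- stats::runif(1, 0, 2 * pi)
    a <- stats::rnorm(1)
    f <- f + a * cos(2 * pi * (fx * co + fy * ro) + ph)
  }
  as.vector(t(f))  # row-major cell order
}

#' Generate correlated environmental layers with a land mask
#'
#' Simulates `nVars` smooth, spatially autocorrelated layers (low-frequency
#' random fields), each standardized to mean 0 / SD 1 over the valid cells,
#' plus one extra `decoy` layer constructed to have Pearson correlation
#' exactly `decoyR` with the first layer over valid cells. About
#' `seaFraction` of cells (the low tail of a separate smooth field, so the
#' "sea" is spatially coherent) are masked out.
#'
#' The generator is a pure function of its arguments and `seed`.
#'
#' @param nRows,nCols grid dimensions.
#' @param nVars number of environmental layers (>= 2), named
#'   `env1 ... envK`.
#' @param decoyR target decoy collinearity, in (0, 1).
#' @param seed integer seed.
#' @param seaFraction fraction of cells masked as sea.
#' @param cellSizeArcmin,origin grid geometry passed to [envGrid()].
#' @return an [EnvGrid] with `nVars + 1` layers (the last named `"decoy"`).
#' @export
makeEnvLayers <- function(nRows, nCols, nVars = 4, decoyR = 0.9, seed = 1,
                          seaFraction = 0.05, cellSizeArcmin = 10,
                          origin = c(0, 0)) {
  stopifnot(nVars >= 2, decoyR > 0, decoyR < 1)
  withr::with_seed(as.integer(seed), {
    sea <- .smoothField(nRows, nCols)
    mask <- sea > stats::quantile(sea, seaFraction)
    std <- function(v) {
      z <- v
      z[!mask] <- NA_real_
      mu <- mean(z[mask]); s <- stats::sd(z[mask])
      z[mask] <- (z[mask] - mu) / s
      z
    }
    layers <- lapply(seq_len(nVars), function(i) std(.smoothField(nRows, nCols)))
    names(layers) <- paste0("env", seq_len(nVars))
    ## decoy: r * env1 + sqrt(1 - r^2) * e, with e a smooth field made
    ## exactly orthonormal to env1 over the valid cells, so the sample
    ## correlation is decoyR exactly and the sample SD is exactly 1.
    e <- std(.smoothField(nRows, nCols))
    z1 <- layers[[1]]
    r1 <- stats::cor(e[mask], z1[mask])
    e[mask] <- e[mask] - r1 * z1[mask]
    e <- std(e)
    d <- z1
    d[mask] <- decoyR * z1[mask] + sqrt(1 - decoyR^2) * e[mask]
    layers$decoy <- d
    envGrid(layers, nRows, nCols, cellSizeArcmin = cellSizeArcmin,
            origin = origin, mask = mask)
  })
}

#' True suitability surface of a virtual species
#'
#' `p(cell) = logistic(beta0 + sum(betaLinear * x) + sum(betaQuadratic *
#' x^2))` over the configured variables. With negative quadratic
#' coefficients this is a unimodal niche with optimum at
#' `-betaLinear / (2 * betaQuadratic)` per gradient.
#'
#' @param grid an [EnvGrid] carrying the configured variables.
#' @param config a [VirtualSpeciesConfig].
#' @return numeric per-cell probability in (0, 1); `NA` on masked cells.
#' @export
trueSuitability <- function(grid, config) {
  v <- config@trueVariables
  miss <- setdiff(v, layerNames(grid))
  if (length(miss))
    stop("grid lacks configured variables: ", paste(miss, collapse = ", "))
  x <- grid@layers[, v, drop = FALSE]
  eta <- config@beta0 + drop(x %*% config@betaLinear) +
    drop(x^2 %*% config@betaQuadratic)
  stats::plogis(eta)
}

#' Sample presence cells proportionally to suitability
#'
#' Draws `n` distinct valid cells without replacement with probability
#' proportional to suitability — one presence per cell, mirroring the
#' gridding rule applied to real occurrence points.
#'
#' @param suitability per-cell suitability (`NA` on masked cells).
#' @param n number of presence cells.
#' @param seed integer seed.
#' @param taxon label for the [PresenceSet].
#' @return a [PresenceSet].
#' @export
samplePresences <- function(suitability, n, seed = 1, taxon = "virtual") {
  ok <- which(!is.na(suitability) & suitability > 0)
  if (n > length(ok))
    stop("cannot draw ", n, " presences from ", length(ok),
         " cells of positive suitability")
  cells <- withr::with_seed(as.integer(seed),
                            sample(ok, n, prob = suitability[ok]))
  presenceSet(cells, taxon = taxon)
}

#' Shift layers to emulate a future climate scenario
#'
#' Adds a per-variable constant to the named layers, keeping geometry and
#' mask. Two presets mimic a moderate and a conservative emissions
#' scenario: `"strong"` shifts every affected layer further than
#' `"mild"`.
#'
#' @param grid an [EnvGrid].
#' @param delta named numeric vector of shifts (layer name -> added
#'   constant), or `NULL` to use a preset.
#' @param preset `"mild"` or `"strong"`; used when `delta` is `NULL`.
#'   Presets shift the temperature-like first gradient up and the second
#'   gradient down (warming plus drying), `strong` twice as far as
#'   `mild`.
#' @return an [EnvGrid] with shifted layers.
#' @export
makeFutureLayers <- function(grid, delta = NULL,
                             preset = c("mild", "strong")) {
  if (is.null(delta)) {
    preset <- match.arg(preset)
    delta <- switch(preset,
      mild = c(env1 = 0.5, env2 = -0.25),
      strong = c(env1 = 1.0, env2 = -0.5))
  }
  miss <- setdiff(names(delta), layerNames(grid))
  if (length(miss))
    stop("delta names not among grid layers: ", paste(miss, collapse = ", "))
  layers <- grid@layers
  for (v in names(delta))
    layers[grid@mask, v] <- layers[grid@mask, v] + delta[[v]]
  envGrid(layers, grid@nRows, grid@nCols,
          cellSizeArcmin = grid@cellSizeArcmin, origin = grid@origin,
          mask = grid@mask)
}

## Shift the niche optimum of the configured surface by `offset` SD units
## along one gradient: substituting x -> (x - offset) in that gradient's
## terms moves the vertex while leaving curvature unchanged.
.shiftOptimum <- function(config, offset) {
  if (offset == 0) return(config)
  g <- match(config@cladeGradient, config@trueVariables)
  bl <- config@betaLinear; bq <- config@betaQuadratic
  b0 <- config@beta0 - bl[g] * offset + bq[g] * offset^2
  bl[g] <- bl[g] - 2 * bq[g] * offset
  methods::initialize(config, beta0 = b0, betaLinear = bl)
}

#' Simulate two clades with offset niche optima
#'
#' Clade 1 is sampled from the configured true suitability; clade 2 from
#' the same surface with its optimum shifted by `config@cladeOffset` SD
#' units along the designated gradient. Clade sizes follow
#' `config@cladeSizes` (clade 2 smaller, as for a restricted secondary
#' invasion).
#'
#' @param grid an [EnvGrid].
#' @param config a [VirtualSpeciesConfig].
#' @param seed integer seed.
#' @return list of two [PresenceSet]s named `clade1`, `clade2`.
#' @export
makeTwoClades <- function(grid, config, seed = 1) {
  seed <- as.integer(seed)
  s1 <- trueSuitability(grid, config)
  s2 <- trueSuitability(grid, .shiftOptimum(config, config@cladeOffset))
  list(
    clade1 = samplePresences(s1, config@cladeSizes[1], seed = seed + 1L,
                             taxon = "clade1"),
    clade2 = samplePresences(s2, config@cladeSizes[2], seed = seed + 2L,
                             taxon = "clade2")
  )
}
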