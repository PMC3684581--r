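## Shared fixtures, built in code.

## Tiny hand-made grid: 3 x 4 cells, two layers, two masked cells.
## Values chosen so every cell is distinct and hand arithmetic is easy.
tinyGrid <- function() {
  v1 <- c(1, 2, 3, 4,
          5, 6, 7, 8,
          9, 10, 11, 12)
  v2 <- v1 / 10
  mask <- rep(TRUE, 12)
  mask[c(4, 9)] <- FALSE
  v1[!mask] <- NA; v2[!mask] <- NA
  envGrid(list(envA = v1, envB = v2), nRows = 3, nCols = 4,
          cellSizeArcmin = 60, origin = c(0, 0), mask = mask)
}

## Small synthetic world for model fitting in unit tests.
smallWorld <- function(seed = 1, nRows = 60, nCols = 60, nVars = 2,
                       nPresence = 120, nBackground = 1200) {
  grid <- makeEnvLayers(nRows, nCols, nVars = nVars, seed = seed)
  cfg <- virtualSpeciesConfig()
  suit <- trueSuitability(grid, cfg)
  list(grid = grid, config = cfg, suit = suit,
       presences = samplePresences(suit, nPresence, seed = seed + 1),
       background = sampleBackground(grid, nBackground, seed = seed + 2))
}

## A training table detached from any grid (for engine-level tests):
## columns cell/label/weight + predictors, weight 1.
plainTable <- function(y, ..., weight = 1) {
  data.frame(cell = seq_along(y), label = as.integer(y),
             weight = rep_len(weight, length(y)), ...)
}

## Brute-force AUC by exhaustive pair counting (independent oracle).
bruteAuc <- function(sp, sa) {
  tot <- 0
  for (p in sp) for (a in sa)
    tot <- tot + (p > a) + 0.5 * (p == a)
  tot / (length(sp) * length(sa))
}

## An oracle "model" whose map is a fixed vector: used to test the
## evaluation protocol independently of any fitting backend.
setClass("FixedMapSDM", contains = "SuitabilityModel",
         representation(map = "numeric"))
setMethod("predictMap", signature("FixedMapSDM", "EnvGrid"),
          function(model, grid) model@map)
fixedMapModel <- function(map) {
  new("FixedMapSDM", family = "FIXED", variables = character(),
      supportsWeights = FALSE, map = pmin(pmax(map, 0), 1))
}
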