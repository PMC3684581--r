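# sdmEnsemble

Ensemble species distribution modelling (SDM) for invasive species under
climate change, with explicit treatment of three sources of predictive
uncertainty:

1. **Assumed species prevalence.** Presence-only data are fitted against a
   large background sample with per-class weights `w_p = φ/n_p`,
   `w_b = (1−φ)/n_b`, so the class totals carry an assumed prevalence φ
   (at φ = 0.9 the presence class weighs 9× the background class; left
   unweighted, 380 presences vs 100,000 background cells would assume
   φ ≈ 0.004). Models are refitted across φ ∈ {0.1, …, 0.9}.
2. **Model family.** Eight suitability models behind one S4 interface —
   GAM (k = 3 smooths), quadratic GLM, CART, boosted regression trees,
   BIOCLIM, DOMAIN, Mahalanobis distance, and a regularized
   presence/background exponential (MAXENT-like) model — all predicting
   in [0, 1] per grid cell. Families are screened by repeated-split
   AUC (80/20 presence splits, equal-sized pseudo-absence draws, 10
   repeats) and retained at mean AUC ≥ 0.9.
3. **Niche differentiation between invasive clades.** An Outlying Mean
   Index (OMI) analysis: marginality `m` = mean standardized environment
   of occupied cells, OMI statistic `‖m‖²`, count-weighted eigenanalysis
   of marginality vectors, one-tailed bootstrap specialization tests,
   and one-sided Welch comparisons of clade occupancy along the leading
   axis and each gradient.

Uncertainty is summarized as cellwise **consensus maps** (median, mean, or
oriented first principal component), **variance maps** across ensemble
members, and four-class **range-change maps** (stable / contraction /
expansion / absent) from binarized current and scenario projections at
the threshold maximizing sensitivity + specificity.

A first-class **virtual-species simulator** (correlated smooth
environmental grids with a land mask, an exactly-collinear decoy layer,
quadratic-logistic true suitability, suitability-proportional presence
sampling, shifted-optimum clade pairs, scenario layer shifts) makes the
whole pipeline testable against known truth. Rasters are read and
written as plain-text ESRI ASCII grids; occurrences as CSV.

## Worked example

```r
library(sdmEnsemble)

grid      <- makeEnvLayers(100, 100, nVars = 4, decoyR = 0.9, seed = 7)
species   <- virtualSpeciesConfig()          # known truth
suit      <- trueSuitability(grid, species)
presences <- samplePresences(suit, 380, seed = 8)
background <- sampleBackground(grid, 5000, seed = 9)

tab <- buildTrainingTable(grid, presences, background, phi = 0.5)
sel <- forwardSelect(tab)                    # GAM forward selection, r >= 0.8 filter
sel$selected
#> [1] "env2" "env1" "env3"
```

The trace shows the collinearity filter removing the decoy (r = 0.9 with
`env1`) before step 3, and the stop at `env4` (not significant, AIC up):

```
  step variable      aic     pValue accepted removed
1    1     env2 7554.722 0.00000000     TRUE
2    2     env1 5456.970 0.00000000     TRUE
3    3     env3 5448.668 0.01296022     TRUE   decoy
4    4     env4 5450.449 0.79434883    FALSE
```

Repeated-split evaluation of the GAM at φ = 0.5 (mean ± sample SD over
10 repeats — AUC is the probability a random presence outscores a random
pseudo-absence; sensitivity/specificity are at the MST threshold):

```r
cvEvaluate(presences, grid, family = "GAM", variables = sel$selected,
           phi = 0.5, nRepeats = 10, seed = 5)
#> EvalReport [GAM, prevalence 0.5]: 10 repeats
#>   auc          0.944 +/- 0.012
#>   sensitivity  0.918 +/- 0.051
#>   specificity  0.862 +/- 0.047
#>   threshold    0.480 +/- 0.084
```

Prevalence sweep, consensus and a range-change projection under the
`strong` warming scenario (this virtual species' optimum lies beyond the
warm edge of today's environment, so warming expands its potential
range):

```r
maps <- lapply(c(0.1, 0.5, 0.9), function(phi) {
  t <- buildTrainingTable(grid, presences, background, phi = phi,
                          variables = sel$selected)
  predictMap(fitGamK3(t), grid)
})
st <- mapStack(grid, setNames(maps, c("phi10", "phi50", "phi90")))
cons <- consensusMap(st, "median")     # the reported consensus
vmap <- varianceMap(st)                # where the phi choice matters

fit <- fitGamK3(buildTrainingTable(grid, presences, background, phi = 0.5,
                                   variables = sel$selected))
cur <- predictMap(fit, grid)
fut <- predictMap(fit, makeFutureLayers(grid, preset = "strong"))
thr <- mstThreshold(c(cur[presenceCells(presences)], cur[background]),
                    rep(c(1, 0), c(380, 5000)))[["threshold"]]
classCounts(rangeChange(grid, binarizeMap(cur, thr), binarizeMap(fut, thr)))
#>      stable contraction   expansion      absent
#>        1689           0         592        7219
```

Two-clade niche overlap (clade 2's optimum sits 1.5 SD warmer along
`env1`; sizes 288/73):

```r
clades <- makeTwoClades(grid, species, seed = 21)
runOMI(grid, clades, background, variables = paste0("env", 1:4),
       nBoot = 999, seed = 3)
#> OMIResult: 2 taxa, 4 axes
#>   axis variance share (%): 99.6, 0.4, 0.0, 0.0
#>   clade1: OMI = 3.229, specialization p = 0.001
#>   clade2: OMI = 4.106, specialization p = 0.001
```

Axis-1 loadings put the shifted temperature-like gradient first
(`env1` 0.752, `env2` 0.642, noise layers ≤ 0.13), and the clades differ
significantly along the axis — both are specialized relative to random
draws of the available environment, and clade 2 occupies the warmer end.

Full orchestrated runs (`runPrevalenceExperiment()`,
`runFamilyExperiment()`, `runCladeAnalysis()`) take a single
configuration (see `inst/extdata/example_config.yaml`), write all maps
as ESRI ASCII, tables as CSV and a JSON manifest with a config hash, and
are byte-identical across reruns with the same seeds.

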