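---
title: "Methods: ensemble SDM uncertainty, prevalence weighting and niche overlap"
author: "sdmEnsemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble SDM uncertainty, prevalence weighting and niche overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Forecasting where an invasive species could establish — now and under
climate change — usually has to work from presence-only occurrence
records. Fitting presence/background models then forces three choices
whose consequences are rarely quantified: the species prevalence the
model implicitly assumes, the statistical model family, and whether
genetically distinct invasive lineages should be modelled as one species
or as separate entities with differentiated niches. `sdmEnsemble`
implements a pipeline that treats all three as explicit sources of
predictive uncertainty: models are refitted across assumed prevalence
levels and across eight model families, their predictions are summarized
by consensus maps and between-model variance maps, binarized ranges are
projected onto climate-change scenarios, and niche differentiation
between two lineages is tested with an Outlying Mean Index (OMI)
analysis.

Everything is exercised end to end on *virtual species*: simulated
organisms with a known true suitability surface, so that each stage can
be validated against truth rather than against an irreproducible data
download.

# Data model

Rasters are regular lat/lon grids (`EnvGrid`): a cells-by-variables
matrix plus a shared land mask, cell IDs row-major from the north-west
corner. The file format is the plain-text ESRI ASCII grid, which keeps
every fixture human-readable and diffable. Occurrence points are CSV
(`lon`, `lat`, optional `clade`); they are converted to grid-cell
presences with set semantics — a cell is a presence whether one or many
points fall in it — using half-open cell intervals (a point on a
boundary belongs to the cell to its south-east), so binning is
deterministic. At a 10 arc-minute resolution a cell spans 18.6 km at the
equator (40,075 km circumference), coarse enough to absorb typical
georeferencing error.

# Prevalence weighting

With presence-only data, models are fitted against a large background
sample of the available environment (default 100,000 cells at global
scale, 5,000 at fixture scale), drawn uniformly without replacement and
*without* excluding presence cells: background is available environment,
not absence. Left unweighted, 380 presences against 100,000 background
rows would implicitly assume a prevalence of 380/100,000 ≈ 0.004.
`classWeights(nP, nB, phi)` instead makes the class *totals* carry the
assumed prevalence: each presence row weighs `phi/nP`, each background
row `(1-phi)/nB`, so the summed presence weight over the summed
background weight is `phi/(1-phi)` — equal classes at `phi = 0.5`, a
9:1 presence excess at `phi = 0.9`. The class-total reading is the only
one under which both of those facts hold at once with unequal row
counts. Weighted likelihoods are scale-invariant but AIC is not, so
training tables rescale weights to sum to the row count; this one
convention makes AIC comparisons across selection steps meaningful.

The prevalence grid {0.1, 0.3, 0.5, 0.7, 0.9} is the default sweep; any
value in (0,1) is accepted.

# Forward variable selection

`forwardSelect()` is greedy forward selection for a weighted binomial
GAM (one smooth per variable with basis dimension k = 3, i.e. capacity
capped near-quadratic) or a quadratic GLM. Step 1 keeps the single
predictor with the highest explained deviance. Before each later step,
candidates with |Pearson r| ≥ 0.8 against any selected predictor are
removed permanently; correlations are computed over the training rows,
unweighted — the background dominates those rows, so this approximates
the collinearity structure of the available environment (the
alternative, all grid cells, is not materially different at our
background sizes). Addition stops when the new term fails a chi-square
test on the weighted deviance drop (degrees of freedom = added
coefficients; alpha = 0.05) or when AIC does not decrease. Exact
deviance ties resolve to the candidate listed first — a documented,
deterministic tie-break. GAMs use REML smoothing selection, under which
duplicating rows while halving weights leaves the fit exactly unchanged
(GCV's explicit n-dependence breaks that equivalence).

# The eight model families

All families fit on the same training table and predict in [0, 1] per
cell, which is what makes consensus and variance maps well defined.

* **GAM** — weighted binomial `mgcv` fit, k = 3 smooths.
* **GLM** — weighted binomial fit on x and x² per variable.
* **CART** — weighted `rpart` classification tree; cost-complexity
  pruning by the internal cross-validation (1-SE rule), leaves predict
  weighted presence proportions. On pure noise this prunes to the root,
  i.e. the weighted prevalence.
* **BRT** — stochastic gradient boosting (`xgboost`) on Bernoulli
  deviance with case weights: learning rate 0.01, depth 3, bag fraction
  0.5; the tree count is chosen by stratified 5-fold cross-validated
  deviance with early stopping and the model refitted on all rows — the
  classic stepwise-BRT recipe. Zero rounds yields the constant
  weighted-prevalence model.
* **BIOCLIM** — percentile envelope: per variable the score is
  `1 - 2|F(x) - 0.5|` with `F` the presence sample's midrank empirical
  CDF (`(#{xi<x} + 0.5 #{xi=x})/n`, which is exactly 0.5 at the sample
  median); the cell score is the minimum over variables and 0 outside
  the presence range of any variable.
* **DOMAIN** — Gower similarity to the most similar presence,
  `1 - mean_v |x_cv - x_pv| / range_v` with ranges over the training
  rows, clamped to [0, 1].
* **MAHAL** — `1 - D²` from the presence mean under the presence
  covariance; the raw score (maximum exactly 1 at the centroid,
  unbounded below) is linearly rescaled over the valid cells of each
  predicted grid so every map spans [0, 1]. The rescale reference is the
  grid being predicted, so current and scenario maps each span the full
  unit range; a fixed current-climate reference would be equally
  defensible but blur the within-scenario contrast we summarize.
* **MAXENT-like** — a regularized presence/background exponential
  model: linear + quadratic features standardized over the background,
  coefficients maximizing the L1-penalized presence log-likelihood
  against the background distribution (penalty `1/sqrt(nP)` per
  feature), solved by proximal gradient descent (soft-thresholding ISTA
  with backtracking; the objective is convex, so initialization at zero
  is canonical). The logistic output `p = e^H q / (1 + e^H q)` (tau =
  0.5), with `q` the cell's relative density and `H` the background
  entropy of the fitted distribution, scores a background-identical
  model 0.5 everywhere. This is a self-contained realization of the
  presence/background exponential-model idea, documented as such rather
  than a port of any particular program.

Presence-only families (BIOCLIM, DOMAIN, MAHAL, MAXENT-like) ignore the
prevalence weights: background rows cannot be weighted into them.
Degenerate inputs fail loudly: constant variables are an error for
DOMAIN's ranges, Mahalanobis' covariance inversion and environment
standardization; `rescaleUnit` refuses constant maps.

# Evaluation and retention

`cvEvaluate()` implements the repeated-split protocol: per repeat the
presence cells split 80/20; the model fits on the training presences
plus an equal-sized pseudo-absence draw and is scored on the held-out
presences plus a disjoint pseudo-absence draw of their size. Equal-sized
test draws avoid the AUC inflation that a huge pseudo-absence sample
produces. Pseudo-absences exclude all presence cells so the test labels
are coherent (a documented choice; background sampling for *fitting*
full models does not exclude them). AUC is Mann–Whitney concordance
(midranks, ties count half). The operating threshold maximizes
sensitivity + specificity, scanned exhaustively over midpoints of
consecutive unique scores plus 0 and 1, ties resolving to the lowest
threshold; sensitivity and specificity are estimated on the test split
at that threshold. Summaries are means with sample SDs over the 10
repeats. `retainModels()` keeps families with mean AUC ≥ 0.9 — an
inclusive bound, so a family at exactly 0.900 is retained; if nothing
qualifies it warns and falls back to the single best family.

# Consensus, variance and range change

`consensusMap()` offers the cellwise median (the default summary),
mean, and the first principal component of the cells-by-members matrix.
PCA sign and scale are not intrinsically fixed, so the axis is oriented
to correlate positively with the cellwise mean and min-max rescaled to
[0, 1]; this makes it directly comparable with the other consensus maps
and leaves it invariant to adding a constant to every member.
`varianceMap()` is the cellwise sample variance (n − 1) across members
— the uncertainty map. Binarization uses the ≥-threshold rule; the
consensus map's threshold is its MST threshold computed against the
training presences plus a fresh background sample, recorded in the run
manifest (the source material does not fix which threshold binarized its
consensus maps; this choice is emitted as metadata so it is auditable).
`rangeChange()` combines binarized current and future maps into the
four classes stable / contraction / expansion / absent, which partition
the valid cells by construction.

# OMI niche analysis

The reference environment is the same background sample used for
modelling; each variable is standardized by the reference mean and SD,
so niche positions are in SD units of the available environment. A
taxon's *marginality* is the mean standardized environment over its
presence cells; its OMI statistic is the squared norm of that vector —
the squared distance between its mean occupied environment and the
average available environment. The ordination eigen-decomposes
`M = sum_k w_k m_k m_k'` with taxon weights proportional to presence
counts (normalized), so the larger clade does not swamp the smaller
through its absolute count but contributes in proportion; the
eigenvalue sum equals the weighted sum of the taxa's OMI statistics (a
trace identity the tests check to 1e-10). Specialization is tested by a
one-tailed bootstrap: the observed OMI statistic against OMI statistics
of uniform same-size draws from the reference cells, with
`p = (1 + #{boot ≥ obs}) / (nBoot + 1)`, so p is never exactly zero.
Clade comparisons are Welch t-tests along the first axis and each raw
gradient, one-sided in the direction of the observed ordering of group
means, with that direction reported alongside the p-value (sidedness
without a stated direction is otherwise ambiguous).

# The virtual-species generator

`makeEnvLayers()` builds smooth spatially autocorrelated layers as
superpositions of 60 random cosine waves with frequencies up to 10
cycles per domain, standardized to mean 0 / SD 1 over the valid cells;
about 5% of cells — the low tail of a separate smooth field, hence a
spatially coherent "sea" — are masked. A decoy layer is constructed by
Gram–Schmidt so its correlation with the first gradient is *exactly*
the requested value (default 0.9) in the realized sample: the
collinearity stress-test for variable selection is thereby exact, not
approximate. The default species is the logistic surface
`eta = 2.2 - 0.3 (x1 - 4)^2 - 0.3 (x2 - 4)^2`: a broad unimodal niche
whose optimum lies beyond the warm/wet edge of the realized
environment. Two properties motivated this geometry, fixed once at
design time: the species is strongly separable from the background (the
true surface's AUC is about 0.92–0.95 across grid realizations), and
suitability still varies learnably over the bulk of cells, so that
tree-based models — which cannot extrapolate a trend beyond their
outermost splits — can rank cells correctly outside the core range.
Extremely sharp niches look superficially "easier" (higher AUC) but
push most of the grid into a region where rank order among vanishing
suitabilities is unlearnable in principle for piecewise-constant
models.

Clade 1 samples from this surface; clade 2 from the same surface with
its optimum shifted 1.5 SD along the temperature-like first gradient
(vertex-form substitution, curvature unchanged), at sizes 288 and 73 —
a widespread primary invader and a restricted secondary one. Presences
are distinct cells drawn without replacement with probability
proportional to suitability, mirroring the one-presence-per-cell
gridding rule. Future scenarios add constant shifts per layer; the
`mild` and `strong` presets move the first gradient up and the second
down (warming plus drying), `strong` twice as far.

What the generator does *not* emulate: the covariance structure of the
19 real bioclimatic variables, continental geometry, spatial sampling
bias in occurrence records, and observation error. Passing tests
therefore demonstrate that the pipeline's machinery is correct and
well-calibrated under known truth — not that any particular real-world
projection is accurate.

# Validation scale

The test suite validates the pipeline at desk scale, chosen as the
smallest sizes at which the statistical claims are stable: a 100 × 100
grid (~9,500 land cells), 300–380 presences, 5,000 background cells,
10-repeat evaluation splits, 50-seed selection experiments, 400-repeat
bootstrap calibration at 199 draws and power checks at 999 draws.
Orchestrated runs write every map as ESRI ASCII, every table as CSV and
a JSON manifest with a config hash, and are byte-identical across
reruns with the same seeds.

# Known limitations

* Geographic lat/lon grids only; no projections, no area weighting of
  cells by latitude.
* The MAXENT-like family uses linear + quadratic features only (matched
  to the other families' capacity); no hinge/threshold features.
* Evaluation splits are random, not spatially blocked, so AUCs inherit
  the usual optimism of non-spatial cross-validation on autocorrelated
  data.
* Ensembles are unweighted (no AUC-weighted averaging), matching the
  consensus definitions implemented here.
* Fitted model objects live in memory for the session; maps and tables,
  not fitted-state serializations, are the persistent artifacts.
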