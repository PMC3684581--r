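## Orchestration of the two uncertainty experiments (prevalence sweep,
## family sweep) and the clade analysis, from a single configuration.

#' Default run configuration
#'
#' All analysis defaults in one list: the prevalence grid
#' (10/30/50/70/90%), the eight model families, the background sample
#' size, the collinearity cut-off (r = 0.8), the significance level, the
#' AUC retention cut-off (0.9) and the 10-repeat 80/20 evaluation
#' protocol. `fixture = TRUE` swaps in desk-scale sizes (100 x 100
#' synthetic grid, 5,000 background cells) suitable for validation runs;
#' the global-scale background of 100,000 cells is the default otherwise.
#'
#' @param fixture use desk-scale synthetic-fixture sizes.
#' @return a named list (a run configuration).
#' @export
defaultRunConfig <- function(fixture = TRUE) {
  list(
    grid = list(source = "synthetic", nRows = 100, nCols = 100, nVars = 4,
                decoyR = 0.9),
    scenarios = c("mild", "strong"),
    prevalences = c(0.1, 0.3, 0.5, 0.7, 0.9),
    families = sdmFamilies(),
    nBackground = if (fixture) 5000 else 100000,
    rMax = 0.8,
    alpha = 0.05,
    aucMin = 0.9,
    nRepeats = 10,
    seed = 1,
    outDir = tempfile("sdmEnsemble_run")
  )
}

#' Read a run configuration from YAML
#'
#' Fields missing from the file fall back to [defaultRunConfig()] values.
#'
#' @param path YAML file.
#' @return a run configuration list.
#' @export
readRunConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  cfg[names(usr)] <- usr
  cfg
}

## Shared setup: grid + scenario grids + presences + background +
## species-level variable selection.
.prepareRun <- function(config) {
  g <- config$grid
  if (!identical(g$source, "synthetic"))
    stop("configure grid$source = 'synthetic', or load rasters with ",
         "loadEnvStack() and call the stage functions directly")
  grid <- makeEnvLayers(g$nRows, g$nCols, nVars = g$nVars,
                        decoyR = g$decoyR, seed = config$seed)
  vs <- virtualSpeciesConfig()
  suit <- trueSuitability(grid, vs)
  presences <- samplePresences(suit, vs@nPresence, seed = config$seed + 10L,
                               taxon = "species")
  background <- sampleBackground(grid, config$nBackground,
                                 seed = config$seed + 20L)
  scen <- lapply(config$scenarios, function(s) makeFutureLayers(grid, preset = s))
  names(scen) <- config$scenarios
  tab <- buildTrainingTable(grid, presences, background, phi = 0.5)
  sel <- forwardSelect(tab, rMax = config$rMax, alpha = config$alpha)
  if (!length(sel$selected))
    stop("forward selection retained no variables")
  list(grid = grid, scenarios = scen, presences = presences,
       background = background, config = vs, selection = sel,
       variables = sel$selected)
}

.writeManifest <- function(outDir, config, files, extra = list()) {
  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, pretty = TRUE)
  manifest <- c(list(configHash = unname(tools::md5sum(cfgPath)),
                     files = files), extra)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

## MST threshold of a consensus map against the training presences plus a
## fresh background sample (the documented binarization choice).
.consensusThreshold <- function(grid, map, presences, seed) {
  bg <- sampleBackground(grid, min(5000L, sum(grid@mask) - 1L), seed = seed)
  bg <- setdiff(bg, presenceCells(presences))
  scores <- c(map[presenceCells(presences)], map[bg])
  labels <- rep(c(1L, 0L), c(length(presenceCells(presences)), length(bg)))
  mstThreshold(scores, labels)[["threshold"]]
}

## Consensus + variance + per-scenario range change for a fitted stack.
.summarizeStack <- function(prep, maps, mapsScen, outDir, tag, seed) {
  grid <- prep$grid
  stack <- mapStack(grid, maps)
  cons <- consensusMap(stack, "median")
  varm <- varianceMap(stack)
  writeEsriAscii(grid, cons, file.path(outDir, paste0(tag, "_consensus_current.asc")))
  writeEsriAscii(grid, varm, file.path(outDir, paste0(tag, "_variance_current.asc")))
  thr <- .consensusThreshold(grid, cons, prep$presences, seed)
  curBin <- binarizeMap(cons, thr)
  files <- c(paste0(tag, "_consensus_current.asc"),
             paste0(tag, "_variance_current.asc"))
  for (s in names(mapsScen)) {
    stackS <- mapStack(grid, mapsScen[[s]])
    consS <- consensusMap(stackS, "median")
    futBin <- binarizeMap(consS, thr)
    rc <- rangeChange(grid, curBin, futBin)
    fns <- paste0(tag, c("_consensus_", "_variance_", "_rangechange_"), s,
                  c(".asc", ".asc", ".csv"))
    writeEsriAscii(grid, consS, file.path(outDir, fns[1]))
    writeEsriAscii(grid, varianceMap(stackS), file.path(outDir, fns[2]))
    writeClassCountsCSV(rc, file.path(outDir, fns[3]))
    files <- c(files, fns)
  }
  list(files = files, threshold = thr, stack = stack)
}

#' Run the prevalence-sweep experiment
#'
#' Fits one GAM per assumed prevalence level on the full
#' presence/background table (forward-selected variables), projects
#' current and scenario suitability, evaluates each prevalence level with
#' the repeated-split protocol, and writes median-consensus, variance and
#' four-class range-change maps plus a manifest.
#'
#' @param config a run configuration (see [defaultRunConfig()]).
#' @return invisibly, a list with the map stack, evaluation reports,
#'   consensus threshold and output file names.
#' @export
runPrevalenceExperiment <- function(config = defaultRunConfig()) {
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  prep <- .prepareRun(config)
  grid <- prep$grid
  maps <- list(); mapsScen <- lapply(prep$scenarios, function(s) list())
  reports <- list()
  for (phi in config$prevalences) {
    id <- sprintf("phi%02d", round(100 * phi))
    tab <- buildTrainingTable(grid, prep$presences, prep$background,
                              phi = phi, variables = prep$variables)
    fit <- fitGamK3(tab, prep$variables)
    maps[[id]] <- predictMap(fit, grid)
    for (s in names(prep$scenarios))
      mapsScen[[s]][[id]] <- predictMap(fit, prep$scenarios[[s]])
    reports[[id]] <- cvEvaluate(prep$presences, grid, family = "GAM",
                                variables = prep$variables, phi = phi,
                                nRepeats = config$nRepeats,
                                seed = config$seed + round(1000 * phi))
  }
  sm <- .summarizeStack(prep, maps, mapsScen, outDir, "prevalence",
                        seed = config$seed + 77L)
  writeEvalCSV(reports, file.path(outDir, "prevalence_performance.csv"))
  writeSelectionTrace(prep$selection, file.path(outDir, "selection_trace.csv"))
  files <- c(sm$files, "prevalence_performance.csv", "selection_trace.csv")
  .writeManifest(outDir, config, files,
                 extra = list(experiment = "prevalence",
                              variables = prep$variables,
                              members = names(maps),
                              threshold = sm$threshold))
  invisible(list(stack = sm$stack, reports = reports,
                 threshold = sm$threshold, files = files, prep = prep))
}

#' Run the model-family experiment
#'
#' Fits all configured families at 50% prevalence on the
#' forward-selected variables, evaluates each with the repeated-split
#' protocol, retains families with mean AUC at or above the cut-off, and
#' writes consensus/variance/range-change maps over the retained members
#' (and, optionally, over all members for contrast).
#'
#' @param config a run configuration.
#' @param allMemberMaps also emit consensus/variance maps over all
#'   families, not only the retained ones.
#' @return invisibly, a list with reports, retained families, stacks and
#'   file names.
#' @export
runFamilyExperiment <- function(config = defaultRunConfig(),
                                allMemberMaps = FALSE) {
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  prep <- .prepareRun(config)
  grid <- prep$grid
  tab <- buildTrainingTable(grid, prep$presences, prep$background,
                            phi = 0.5, variables = prep$variables)
  maps <- list(); mapsScen <- lapply(prep$scenarios, function(s) list())
  reports <- list()
  for (fam in config$families) {
    fit <- withr::with_seed(config$seed + 300L, fitModel(tab, fam, prep$variables))
    maps[[fam]] <- predictMap(fit, grid)
    for (s in names(prep$scenarios))
      mapsScen[[s]][[fam]] <- predictMap(fit, prep$scenarios[[s]])
    reports[[fam]] <- cvEvaluate(prep$presences, grid, family = fam,
                                 variables = prep$variables, phi = 0.5,
                                 nRepeats = config$nRepeats,
                                 seed = config$seed + 200L)
  }
  retained <- retainModels(reports, aucMin = config$aucMin)
  sm <- .summarizeStack(prep, maps[retained],
                        lapply(mapsScen, function(m) m[retained]),
                        outDir, "family_retained", seed = config$seed + 88L)
  files <- sm$files
  if (allMemberMaps) {
    smAll <- .summarizeStack(prep, maps, mapsScen, outDir, "family_all",
                             seed = config$seed + 88L)
    files <- c(files, smAll$files)
  }
  writeEvalCSV(reports, file.path(outDir, "family_performance.csv"))
  files <- c(files, "family_performance.csv")
  .writeManifest(outDir, config, files,
                 extra = list(experiment = "family", retained = retained,
                              variables = prep$variables,
                              threshold = sm$threshold))
  invisible(list(reports = reports, retained = retained, stack = sm$stack,
                 threshold = sm$threshold, files = files, prep = prep))
}

#' Run the two-clade niche and projection analysis
#'
#' Simulates the two clades (offset niche optima, asymmetric sizes), fits
#' a 50%-prevalence GAM per clade on the species-level selected variables
#' (variable selection is done once at species level and reused), writes
#' per-clade current/future range-change maps, and runs the OMI
#' niche-overlap analysis of the two clades against the background
#' reference.
#'
#' @param config a run configuration.
#' @return invisibly, a list with the [OMIResult], per-clade potential
#'   range areas (current cells in range) and file names.
#' @export
runCladeAnalysis <- function(config = defaultRunConfig()) {
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  prep <- .prepareRun(config)
  grid <- prep$grid
  clades <- makeTwoClades(grid, prep$config, seed = config$seed + 40L)
  areas <- numeric(); files <- character()
  for (nm in names(clades)) {
    tab <- buildTrainingTable(grid, clades[[nm]], prep$background,
                              phi = 0.5, variables = prep$variables)
    fit <- fitGamK3(tab, prep$variables)
    cur <- predictMap(fit, grid)
    thr <- .consensusThreshold(grid, cur, clades[[nm]],
                               seed = config$seed + 99L)
    curBin <- binarizeMap(cur, thr)
    areas[nm] <- sum(curBin == 1L, na.rm = TRUE)
    writeEsriAscii(grid, cur, file.path(outDir, paste0(nm, "_current.asc")))
    files <- c(files, paste0(nm, "_current.asc"))
    for (s in names(prep$scenarios)) {
      futBin <- binarizeMap(predictMap(fit, prep$scenarios[[s]]), thr)
      rc <- rangeChange(grid, curBin, futBin)
      fn <- paste0(nm, "_rangechange_", s, ".csv")
      writeClassCountsCSV(rc, file.path(outDir, fn))
      files <- c(files, fn)
    }
  }
  omi <- runOMI(grid, clades, prep$background,
                variables = setdiff(layerNames(grid), "decoy"),
                seed = config$seed + 50L)
  writeOMICSV(omi, outDir)
  files <- c(files, "omi_loadings.csv", "omi_taxa.csv", "omi_pairwise.csv")
  .writeManifest(outDir, config, files,
                 extra = list(experiment = "clades",
                              variables = prep$variables,
                              rangeAreas = as.list(areas)))
  invisible(list(omi = omi, areas = areas, files = files, prep = prep))
}
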