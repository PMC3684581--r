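## Outlying Mean Index (OMI) niche analysis. The reference environment is
## a background sample of the available environment; marginality is a
## taxon's mean position in the standardized environmental space, the OMI
## statistic its squared norm, and the ordination the eigenanalysis of the
## count-weighted marginality outer products.

#' Standardize an environmental table against a reference
#'
#' Centers and scales each variable by the reference rows' mean and SD,
#' so marginality is measured in SD units of the available environment.
#'
#' @param x reference matrix/data.frame (cells x variables).
#' @return list with `Z` (standardized matrix), `center`, `scale`.
#' @export
standardizeEnv <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0))
    stop("constant variable(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "))
  list(Z = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Apply a reference standardization to new rows
#'
#' @param x matrix of environmental values (e.g. presence cells).
#' @param std a standardization from [standardizeEnv()].
#' @return standardized matrix.
#' @export
applyStandardization <- function(x, std) {
  sweep(sweep(as.matrix(x), 2, std$center), 2, std$scale, "/")
}

#' Marginality vector of a taxon
#'
#' The taxon's niche position: mean standardized environmental conditions
#' over its presence cells (uniform occurrence weights).
#'
#' @param z standardized environmental values of the presence cells
#'   (rows).
#' @return numeric vector over variables.
#' @export
marginality <- function(z) colMeans(as.matrix(z))

#' OMI statistic of a taxon
#'
#' Squared Euclidean norm of the marginality vector: the squared distance
#' between the taxon's mean occupied environment and the average available
#' environment, in standardized units.
#'
#' @inheritParams marginality
#' @return non-negative scalar.
#' @export
omiStatistic <- function(z) sum(marginality(z)^2)

#' OMI ordination of one or more taxa
#'
#' Eigen-decomposition of `M = sum_k w_k m_k m_k'`, where `m_k` is taxon
#' k's marginality vector and the taxon weights `w_k` are proportional to
#' presence counts (normalized to sum 1). The leading eigenvectors are the
#' environmental directions that best separate the taxa's mean occupied
#' conditions from the average environment; any cell's axis score is its
#' standardized row times the axis loading vector.
#'
#' @param zList list of standardized presence matrices, one per taxon.
#' @return list with `axes` (variables x axes, unit-norm loadings),
#'   `eigenvalues` (decreasing), `varianceShare` (% of total, sums to
#'   100), `weights`, and `marginalities` (taxa x variables).
#' @export
omiOrdination <- function(zList) {
  if (length(zList) < 1L) stop("need at least one taxon")
  M <- t(vapply(zList, marginality, numeric(ncol(as.matrix(zList[[1]])))))
  if (is.null(colnames(M))) colnames(M) <- colnames(as.matrix(zList[[1]]))
  w <- vapply(zList, function(z) nrow(as.matrix(z)), 0)
  w <- w / sum(w)
  S <- crossprod(M * sqrt(w))  # = sum_k w_k m_k m_k'
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  list(axes = eg$vectors, eigenvalues = ev,
       varianceShare = 100 * ev / sum(ev), weights = w, marginalities = M)
}

#' One-tailed bootstrap test of niche specialization
#'
#' Compares a taxon's observed OMI statistic to the distribution obtained
#' by drawing random cell sets of the same size uniformly from the
#' reference environment: `p = (1 + #{boot >= observed}) / (nBoot + 1)`.
#'
#' @param zRef standardized reference matrix (background cells).
#' @param zTaxon standardized presence matrix of the taxon.
#' @param nBoot number of bootstrap draws (>= 1).
#' @param seed integer seed.
#' @return one-tailed p-value in (0, 1].
#' @export
specializationTest <- function(zRef, zTaxon, nBoot = 1000, seed = 1) {
  if (nBoot < 1L) stop("nBoot must be at least 1")
  zRef <- as.matrix(zRef); zTaxon <- as.matrix(zTaxon)
  obs <- omiStatistic(zTaxon)
  n <- nrow(zTaxon)
  boot <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nBoot), function(b) {
      omiStatistic(zRef[sample(nrow(zRef), n), , drop = FALSE])
    }, 0)
  })
  (1 + sum(boot >= obs)) / (nBoot + 1)
}

#' One-sided Welch comparison of two clades
#'
#' Welch two-sample t-test per column, tested in the direction of the
#' observed ordering of group means (reported alongside the p-value).
#'
#' @param x1,x2 numeric matrices (rows = presence cells) with matching
#'   columns, or vectors.
#' @return data.frame with `variable`, `t`, `direction`
#'   (`"clade1>clade2"` or `"clade1<clade2"`), `p`.
#' @export
cladeComparison <- function(x1, x2) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  stopifnot(ncol(x1) == ncol(x2))
  nm <- colnames(x1)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(x1)))
  rows <- lapply(seq_len(ncol(x1)), function(j) {
    a <- x1[, j]; b <- x2[, j]
    alt <- if (mean(a) >= mean(b)) "greater" else "less"
    tt <- stats::t.test(a, b, alternative = alt)
    data.frame(variable = nm[j], t = unname(tt$statistic),
               direction = if (alt == "greater") "clade1>clade2"
                           else "clade1<clade2",
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full OMI niche-overlap analysis
#'
#' Standardizes the environment against a background reference, runs the
#' OMI ordination over the given taxa, computes per-taxon niche position
#' and breadth along each axis, OMI statistics with one-tailed bootstrap
#' specialization p-values, and (when exactly two clades plus optionally
#' the pooled species are given) pairwise one-sided Welch comparisons of
#' the first-axis scores and of each environmental gradient between the
#' first two taxa.
#'
#' @param grid an [EnvGrid].
#' @param presenceSets list of [PresenceSet]s (first two are the compared
#'   clades).
#' @param backgroundCells integer cell IDs of the reference environment
#'   sample (see [sampleBackground()]).
#' @param variables environmental layers to analyse.
#' @param nBoot bootstrap draws for the specialization test.
#' @param seed integer seed.
#' @return an [OMIResult].
#' @export
runOMI <- function(grid, presenceSets, backgroundCells,
                   variables = layerNames(grid), nBoot = 1000, seed = 1) {
  stopifnot(length(presenceSets) >= 1L)
  ref <- grid@layers[backgroundCells, variables, drop = FALSE]
  std <- standardizeEnv(ref)
  zTaxa <- lapply(presenceSets, function(p)
    applyStandardization(grid@layers[presenceCells(p), variables,
                                     drop = FALSE], std))
  taxa <- unname(vapply(presenceSets, function(p) p@taxon, ""))
  names(zTaxa) <- taxa
  ord <- omiOrdination(zTaxa)
  rownames(ord$axes) <- variables
  colnames(ord$axes) <- paste0("OMI", seq_len(ncol(ord$axes)))
  scores <- lapply(zTaxa, function(z) z %*% ord$axes)
  pos <- t(vapply(scores, colMeans, numeric(ncol(ord$axes))))
  brd <- t(vapply(scores, function(s) apply(s, 2, stats::sd),
                  numeric(ncol(ord$axes))))
  dimnames(pos) <- dimnames(brd) <- list(taxa, colnames(ord$axes))
  omi <- vapply(zTaxa, omiStatistic, 0)
  pSpec <- vapply(seq_along(zTaxa), function(i)
    specializationTest(std$Z, zTaxa[[i]], nBoot = nBoot,
                       seed = as.integer(seed) + i), 0)
  names(omi) <- names(pSpec) <- taxa
  if (length(zTaxa) >= 2L) {
    ax <- cladeComparison(scores[[1]][, 1, drop = FALSE],
                          scores[[2]][, 1, drop = FALSE])
    ax$variable <- "OMI1"
    pv <- cladeComparison(zTaxa[[1]], zTaxa[[2]])
  } else {
    ax <- pv <- data.frame(variable = character(), t = numeric(),
                           direction = character(), p = numeric())
  }
  new("OMIResult", axes = ord$axes, eigenvalues = ord$eigenvalues,
      varianceShare = ord$varianceShare, taxa = taxa,
      weights = unname(ord$weights), nichePosition = pos,
      nicheBreadth = brd, omiStat = omi, specializationP = pSpec,
      pairwiseAxis = ax, pairwiseVariables = pv)
}

#' Write OMI outputs as CSV tables
#'
#' Three files: axis loadings (one row per variable, sorted by axis-1
#' loading), per-taxon position/breadth/OMI/p, and per-variable pairwise
#' tests.
#'
#' @param x an [OMIResult].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
writeOMICSV <- function(x, dir, prefix = "omi") {
  ld <- data.frame(variable = rownames(x@axes), x@axes, row.names = NULL)
  ld <- ld[order(ld$OMI1), ]
  utils::write.csv(ld, file.path(dir, paste0(prefix, "_loadings.csv")),
                   row.names = FALSE)
  tx <- data.frame(taxon = x@taxa, position_OMI1 = x@nichePosition[, 1],
                   breadth_OMI1 = x@nicheBreadth[, 1], omi = x@omiStat,
                   specialization_p = x@specializationP, row.names = NULL)
  utils::write.csv(tx, file.path(dir, paste0(prefix, "_taxa.csv")),
                   row.names = FALSE)
  utils::write.csv(rbind(x@pairwiseAxis, x@pairwiseVariables),
                   file.path(dir, paste0(prefix, "_pairwise.csv")),
                   row.names = FALSE)
  invisible(dir)
}
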