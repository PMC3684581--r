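refZ <- function(n = 500, v = 3, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(n * v), n, v,
                                dimnames = list(NULL, paste0("v", 1:v))))
}

test_that("environment standardization centers, scales and round-trips", {
  x <- refZ(200, 3, seed = 2) * 5 + 2
  std <- standardizeEnv(x)
  expect_equal(unname(colMeans(std$Z)), rep(0, 3))
  expect_equal(unname(apply(std$Z, 2, sd)), rep(1, 3))
  back <- sweep(sweep(std$Z, 2, std$scale, "*"), 2, std$center, "+")
  expect_equal(back, x)
  xBad <- cbind(x, const = 1)
  expect_error(standardizeEnv(xBad), "constant")
})

test_that("marginality is the mean standardized condition of occupied cells", {
  std <- standardizeEnv(refZ(100, 2, seed = 3))
  # a taxon occupying every reference cell sits at the origin
  expect_equal(unname(marginality(std$Z)), c(0, 0))
  # hand fixture: 4 cells, occupying rows 1 and 3
  Z <- matrix(c(1, 2, 3, 4,
                10, 20, 30, 40), 4, 2)
  expect_equal(unname(marginality(Z[c(1, 3), ])), c(2, 20))
  expect_equal(omiStatistic(Z[c(1, 3), ]), 2^2 + 20^2)
})

test_that("the OMI statistic is rotation-invariant and zero for the full set", {
  std <- standardizeEnv(refZ(300, 3, seed = 4))
  expect_lt(omiStatistic(std$Z), 1e-20)
  z <- std$Z[1:40, ]
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(omiStatistic(z %*% R), omiStatistic(z))
})

test_that("OMI ordination handles rank-1 and symmetric two-taxon cases", {
  # one taxon: the single axis is its marginality direction, 100% variance
  z1 <- sweep(refZ(50, 3, seed = 5), 2, c(2, 1, 0), "+")
  ord1 <- omiOrdination(list(z1))
  expect_equal(ord1$varianceShare[1], 100)
  m <- marginality(z1)
  expect_equal(abs(sum(ord1$axes[, 1] * m / sqrt(sum(m^2)))), 1)
  # two taxa with orthogonal equal-norm marginalities and equal counts
  za <- sweep(refZ(80, 2, seed = 6), 2, c(1.5, 0), "+")
  zb <- sweep(refZ(80, 2, seed = 7), 2, c(0, 1.5), "+")
  za[, 2] <- za[, 2] - mean(za[, 2]); za[, 1] <- za[, 1] - mean(za[, 1]) + 1.5
  zb[, 1] <- zb[, 1] - mean(zb[, 1]); zb[, 2] <- zb[, 2] - mean(zb[, 2]) + 1.5
  ord2 <- omiOrdination(list(za, zb))
  expect_equal(ord2$varianceShare, c(50, 50))
  expect_error(omiOrdination(list()), "at least one")
})

test_that("the ordination eigenvalues satisfy the trace identity", {
  for (k in 1:10) {
    withr::with_seed(400 + k, {
      nT <- sample(2:4, 1)
      zs <- lapply(seq_len(nT), function(i)
        sweep(matrix(rnorm(60 * 3), 60, 3), 2, rnorm(3), "+"))
    })
    ord <- omiOrdination(zs)
    w <- vapply(zs, nrow, 0); w <- w / sum(w)
    lhs <- sum(ord$eigenvalues)
    rhs <- sum(w * vapply(zs, omiStatistic, 0))
    expect_lt(abs(lhs - rhs), 1e-10)
    expect_equal(sum(ord$varianceShare), 100)
  }
})

test_that("the specialization bootstrap is valid under the null and powerful when shifted", {
  std <- standardizeEnv(refZ(600, 3, seed = 8))
  expect_error(specializationTest(std$Z, std$Z[1:10, ], nBoot = 0), "nBoot")
  # null: a taxon that is itself a uniform draw from the reference
  pvals <- vapply(1:120, function(k) {
    zT <- withr::with_seed(500 + k, std$Z[sample(600, 50), ])
    specializationTest(std$Z, zT, nBoot = 199, seed = 700 + k)
  }, 0)
  expect_true(all(pvals > 0 & pvals <= 1))
  rate <- mean(pvals <= 0.05)
  expect_lt(abs(rate - 0.05), 2.58 * sqrt(0.05 * 0.95 / 120) + 1e-9)
  # a clearly displaced taxon is detected
  zShift <- sweep(std$Z[1:50, ], 2, c(2, 0, 0), "+")
  expect_lte(specializationTest(std$Z, zShift, nBoot = 999, seed = 1),
             0.001)
})

test_that("seed-averaged specialization p decreases with the niche offset", {
  g <- makeEnvLayers(60, 60, nVars = 3, seed = 12)
  bg <- sampleBackground(g, 1500, seed = 13)
  vars <- paste0("env", 1:3)
  std <- standardizeEnv(g@layers[bg, vars])
  meanP <- vapply(c(0, 0.5, 1.5), function(off) {
    cfg <- virtualSpeciesConfig(trueVariables = "env1", beta0 = 0,
                                betaLinear = 2 * off, betaQuadratic = -1,
                                cladeGradient = "env1")
    suit <- trueSuitability(g, cfg)
    mean(vapply(1:20, function(k) {
      p <- samplePresences(suit, 80, seed = 900 + k)
      zT <- applyStandardization(g@layers[presenceCells(p), vars], std)
      specializationTest(std$Z, zT, nBoot = 199, seed = 950 + k)
    }, 0))
  }, 0)
  expect_true(meanP[1] > meanP[2] && meanP[2] > meanP[3])
})

test_that("clade comparisons are one-sided Welch tests in the observed direction", {
  expect_equal(cladeComparison(cbind(x = c(1, 2, 3)),
                               cbind(x = c(1, 2, 3)))$t, 0)
  expect_equal(cladeComparison(cbind(x = c(1, 2, 3)),
                               cbind(x = c(1, 2, 3)))$p, 0.5)
  rej <- vapply(1:200, function(k) {
    withr::with_seed(1200 + k, {
      a <- rnorm(100); b <- rnorm(100, 1)
    })
    cladeComparison(cbind(x = a), cbind(x = b))$p < 0.001
  }, TRUE)
  expect_gte(mean(rej), 0.99)
})

test_that("runOMI assembles a coherent result for two clades", {
  g <- makeEnvLayers(60, 60, nVars = 3, seed = 14)
  cl <- makeTwoClades(g, virtualSpeciesConfig(cladeSizes = c(80, 40)),
                      seed = 15)
  bg <- sampleBackground(g, 1500, seed = 16)
  omi <- runOMI(g, cl, bg, variables = paste0("env", 1:3), nBoot = 99,
                seed = 17)
  expect_s4_class(omi, "OMIResult")
  expect_identical(omi@taxa, c("clade1", "clade2"))
  expect_equal(sum(omi@varianceShare), 100)
  expect_equal(unname(colSums(omi@axes^2)), rep(1, 3))
  expect_equal(unname(omi@weights), c(80, 40) / 120)
  expect_true(all(omi@nicheBreadth >= 0))
  expect_true(all(omi@specializationP > 0 & omi@specializationP <= 1))
  expect_identical(omi@pairwiseAxis$variable, "OMI1")
  expect_identical(omi@pairwiseVariables$variable, paste0("env", 1:3))
  d <- withr::local_tempdir()
  writeOMICSV(omi, d)
  expect_true(all(file.exists(file.path(d, c("omi_loadings.csv",
                                             "omi_taxa.csv",
                                             "omi_pairwise.csv")))))
})
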