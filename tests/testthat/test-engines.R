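test_that("rescaleUnit is the stated linear transform", {
  expect_equal(rescaleUnit(c(-5, 0, 1)), c(0, 5 / 6, 1))
  expect_equal(rescaleUnit(c(0, 0.3, 1)), c(0, 0.3, 1))
  withr::with_seed(1, v <- rnorm(50))
  r <- rescaleUnit(v)
  expect_equal(min(r), 0); expect_equal(max(r), 1)
  expect_error(rescaleUnit(rep(2, 5)), "constant")
})

test_that("intercept-only weighted fits predict the assumed prevalence", {
  w <- smallWorld(seed = 2)
  for (phi in c(0.3, 0.7)) {
    tab <- buildTrainingTable(w$grid, w$presences, w$background, phi = phi)
    for (fam in c("GAM", "GLM")) {
      m <- fitModel(tab, fam, variables = character(0))
      expect_equal(unique(round(predictMap(m, w$grid)[w$grid@mask], 8)), phi,
                   tolerance = 1e-6)
    }
  }
})

test_that("duplicating rows with halved weights leaves GAM/GLM predictions unchanged", {
  w <- smallWorld(seed = 3)
  tab <- buildTrainingTable(w$grid, w$presences, w$background, phi = 0.5,
                            variables = c("env1", "env2"))
  tab2 <- rbind(tab, tab); tab2$weight <- tab2$weight / 2
  for (fam in c("GAM", "GLM")) {
    m1 <- fitModel(tab, fam); m2 <- fitModel(tab2, fam)
    expect_equal(predictMap(m1, w$grid), predictMap(m2, w$grid),
                 tolerance = 1e-6)
  }
})

test_that("quadratic GLM recovers the generating coefficients at large n", {
  withr::with_seed(41, {
    n <- 20000
    x1 <- rnorm(n)
    beta <- c(b0 = 0.5, b1 = 1.5, b2 = -0.8)
    y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x1 + beta[3] * x1^2))
    tab <- plainTable(y, x1 = x1)
  })
  m <- fitGlmQuadratic(tab)
  est <- coef(m@fit)
  expect_identical(sign(unname(est)), sign(unname(beta)))
  expect_lt(max(abs((est - beta) / beta)), 0.2)
})

test_that("CART separates a perfectly separating variable and prunes pure noise", {
  withr::with_seed(7, {
    x <- c(runif(150, -2, -0.1), runif(150, 0.1, 2))
    y <- as.integer(x > 0)
    tab <- plainTable(y, x = x)
  })
  set.seed(1)
  m <- fitCart(tab)
  expect_identical(nrow(m@fit$frame[m@fit$frame$var == "<leaf>", ]), 2L)
  g1 <- envGrid(list(x = seq(-2, 2, length.out = 100)), 10, 10,
                cellSizeArcmin = 60, origin = c(0, 0))
  pr <- predictMap(m, g1)
  expect_setequal(unique(pr), c(0, 1))
  expect_equal(aucScore(pr[g1@layers[, "x"] > 0], pr[g1@layers[, "x"] < 0]), 1)
  # pure noise: pruned back to the root, predicting the weighted prevalence
  rootRate <- vapply(1:50, function(k) {
    withr::with_seed(100 + k, {
      tabN <- plainTable(rbinom(200, 1, 0.35), x1 = rnorm(200), x2 = rnorm(200))
      mN <- fitCart(tabN)
      nrow(mN@fit$frame) == 1L
    })
  }, TRUE)
  expect_gte(mean(rootRate), 0.9)
})

test_that("CART trees are invariant to weight scale", {
  w <- smallWorld(seed = 4)
  tab <- buildTrainingTable(w$grid, w$presences, w$background, phi = 0.5,
                            variables = c("env1", "env2"))
  tab2 <- tab; tab2$weight <- tab2$weight * 2
  set.seed(11); m1 <- fitCart(tab)
  set.seed(11); m2 <- fitCart(tab2)
  expect_equal(predictMap(m1, w$grid), predictMap(m2, w$grid))
})

test_that("BRT training deviance is non-increasing and zero rounds gives the prevalence", {
  withr::with_seed(9, {
    x <- rnorm(400)
    y <- rbinom(400, 1, plogis(2 * x))
    tab <- plainTable(y, x = x)
  })
  d <- xgboost::xgb.DMatrix(as.matrix(tab[, "x", drop = FALSE]),
                            label = tab$label, weight = tab$weight,
                            nthread = 1)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = 0.05, max_depth = 3,
                  nthread = 1),
    data = d, nrounds = 100, evals = list(train = d), verbose = 0)
  log <- attributes(fit)$evaluation_log$train_logloss
  expect_true(all(diff(log) <= 1e-8))
  # zero boosting iterations: the constant weighted-prevalence model
  w <- smallWorld(seed = 5)
  tabW <- buildTrainingTable(w$grid, w$presences, w$background, phi = 0.5,
                             variables = c("env1", "env2"))
  m0 <- fitBrt(tabW, nRoundsMax = 0)
  p0 <- sum(tabW$weight * tabW$label) / sum(tabW$weight)
  expect_equal(unique(predictMap(m0, w$grid)[w$grid@mask]), p0)
})

test_that("BRT recovers a smooth monotone signal", {
  withr::with_seed(13, {
    x <- rnorm(2000)
    y <- rbinom(2000, 1, plogis(2 * x))
    tab <- plainTable(y, x = x)
  })
  set.seed(2)
  m <- fitBrt(tab)
  g1 <- envGrid(list(x = seq(-2.5, 2.5, length.out = 400)), 20, 20,
                cellSizeArcmin = 60, origin = c(0, 0))
  ord <- order(g1@layers[, "x"])
  pr <- predictMap(m, g1)[ord]
  # isotonic check: departure from the isotonic (PAVA) fit stays within
  # tolerance, i.e. any non-monotone wiggle is small on average
  iso <- stats::isoreg(sort(g1@layers[, "x"]), pr)
  expect_lte(mean(abs(pr - iso$yf)), 0.02)
  # and the overall trend is strongly increasing
  expect_gt(cor(pr, sort(g1@layers[, "x"]), method = "spearman"), 0.95)
})

test_that("BIOCLIM scores follow the percentile-envelope formula", {
  # 5-presence, 2-variable toy with hand-computable percentiles
  pv1 <- c(1, 2, 3, 4, 5); pv2 <- c(10, 20, 30, 40, 50)
  tab <- plainTable(rep(1, 5), v1 = pv1, v2 = pv2)
  m <- fitBioclim(tab)
  gTest <- envGrid(list(v1 = c(3, 3, 6, 2), v2 = c(30, 30, 30, 20)),
                   2, 2, cellSizeArcmin = 60, origin = c(0, 0))
  s <- predictMap(m, gTest)
  # cell at the presence median of both variables scores 1
  expect_equal(s[1], 1)
  # beyond the presence max of one variable scores 0
  expect_equal(s[3], 0)
  # hand formula: F(2) = (1 + 0.5)/5 = 0.3 -> 1 - 2|0.3 - 0.5| = 0.6;
  # F(20) = 0.3 -> 0.6; min(0.6, 0.6) = 0.6
  expect_equal(s[4], 0.6)
})

test_that("DOMAIN is the max Gower similarity over presences", {
  tab1 <- plainTable(c(1, 0, 0), v = c(0, 5, 10))
  m1 <- fitDomain(tab1)
  gTest <- envGrid(list(v = c(0, 5, 10, 2.5)), 2, 2,
                   cellSizeArcmin = 60, origin = c(0, 0))
  s <- predictMap(m1, gTest)
  expect_equal(s[1], 1)      # identical to the presence
  expect_equal(s[2], 0.5)    # 5 units away with range 10
  expect_equal(s[3], 0)      # 10 units away
  # 3 presences, 2 variables: brute force over all presences
  withr::with_seed(3, {
    pv <- matrix(runif(6), 3, 2)
    cells <- matrix(runif(8), 4, 2)
  })
  tab2 <- plainTable(c(1, 1, 1, 0, 0, 0, 0),
                     a = c(pv[, 1], cells[, 1]),
                     b = c(pv[, 2], cells[, 2]))
  m2 <- fitDomain(tab2)
  rngA <- diff(range(tab2$a)); rngB <- diff(range(tab2$b))
  gTest2 <- envGrid(list(a = cells[, 1], b = cells[, 2]), 2, 2,
                    cellSizeArcmin = 60, origin = c(0, 0))
  s2 <- predictMap(m2, gTest2)
  brute <- apply(cells, 1, function(cc) {
    max(apply(pv, 1, function(p)
      1 - mean(c(abs(cc[1] - p[1]) / rngA, abs(cc[2] - p[2]) / rngB))))
  })
  expect_equal(s2, pmin(pmax(brute, 0), 1))
})

test_that("Mahalanobis raw scores are 1 - D^2 and maps are rescaled to [0, 1]", {
  withr::with_seed(5, {
    pv <- matrix(rnorm(200), 100, 2)
    pv <- sweep(pv, 2, colMeans(pv))  # centroid exactly at the origin
  })
  tab <- plainTable(rep(1, 100), a = pv[, 1], b = pv[, 2])
  m <- fitMahalanobis(tab)
  gTest <- envGrid(list(a = c(0, 2, -1, 1), b = c(0, 0, 1, -1)), 2, 2,
                   cellSizeArcmin = 60, origin = c(0, 0))
  raw <- mahalRawScores(m, gTest)
  expect_equal(raw[1], 1)  # the centroid scores the maximum, D^2 = 0
  # identity covariance, distance 2 on one axis: raw = 1 - 4 = -3
  tabI <- plainTable(rep(1, 4), a = c(1, -1, 0, 0), b = c(0, 0, 1, -1))
  tabI[, c("a", "b")] <- tabI[, c("a", "b")] * sqrt(3) / sqrt(2)  # unit cov
  mI <- fitMahalanobis(tabI)
  expect_equal(unname(mahalRawScores(mI, gTest)[2]), -3)
  mp <- predictMap(m, gTest)
  expect_equal(min(mp), 0); expect_equal(max(mp), 1)
  # degenerate variable: singular covariance is an explicit error
  tabBad <- plainTable(rep(1, 10), a = rnorm(10), b = rep(2, 10))
  expect_error(fitMahalanobis(tabBad), "degenerate|singular")
})

test_that("the exponential presence/background model behaves like a null at uniformity", {
  withr::with_seed(21, {
    xb <- rnorm(1000)
    xp <- sample(xb, 300)   # presences indistinguishable from background
    tab <- plainTable(c(rep(1, 300), rep(0, 1000)), x = c(xp, xb))
  })
  m <- fitMaxentLike(tab)
  g1 <- envGrid(list(x = seq(-2, 2, length.out = 100)), 10, 10,
                cellSizeArcmin = 60, origin = c(0, 0))
  pr <- predictMap(m, g1)
  expect_lt(max(abs(pr - 0.5)), 0.05)
})

test_that("the exponential model tracks concentrated presences with output in (0, 1)", {
  withr::with_seed(22, {
    xb <- rnorm(2000)
    w <- exp(2 * xb); xp <- sample(xb, 300, prob = w / sum(w))
    tab <- plainTable(c(rep(1, 300), rep(0, 2000)), x = c(xp, xb))
  })
  m <- fitMaxentLike(tab)
  expect_gt(m@coef[1], 0)  # linear feature coefficient positive
  g1 <- envGrid(list(x = seq(-3, 3, length.out = 100)), 10, 10,
                cellSizeArcmin = 60, origin = c(0, 0))
  pr <- predictMap(m, g1)
  expect_true(all(pr > 0 & pr < 1))
  expect_gt(pr[which.max(g1@layers[, "x"])], pr[which.min(g1@layers[, "x"])])
})

test_that("prediction is deterministic, variable-faithful and in [0, 1] for all families", {
  w <- smallWorld(seed = 6)
  tab <- buildTrainingTable(w$grid, w$presences, w$background, phi = 0.5,
                            variables = c("env1", "env2"))
  gCopy <- envGrid(w$grid@layers, w$grid@nRows, w$grid@nCols,
                   cellSizeArcmin = w$grid@cellSizeArcmin,
                   origin = w$grid@origin, mask = w$grid@mask)
  gPerturb <- makeFutureLayers(w$grid, delta = c(env2 = 2))
  for (fam in sdmFamilies()) {
    set.seed(31)
    m <- fitModel(tab, fam)
    p1 <- predictMap(m, w$grid)
    expect_identical(p1, predictMap(m, gCopy))
    v <- p1[w$grid@mask]
    expect_true(all(v >= 0 & v <= 1), info = fam)
    expect_true(all(is.na(p1[!w$grid@mask])), info = fam)
    if (fam %in% c("GAM", "GLM")) {
      mE1 <- fitModel(tab, fam, variables = "env1")
      expect_identical(predictMap(mE1, w$grid), predictMap(mE1, gPerturb))
    }
  }
})
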