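# Prior discretization, marginal likelihood, gradients, chromosome splits,
# boosted fitting, hyperparameter search, and persistence.

test_that("discretized priors normalize and hit their limits", {
  grid <- defaultSelectionGrid()
  w <- discretizePrior(c(-3, log(0.5)), grid)
  expect_sums_to_one(w)
  expect_true(all(w >= 0))

  # flat-density limit: interior weights approach uniformity within 1%
  wFlat <- discretizePrior(c(-4, log(1000)), grid)
  interior <- wFlat[2:(length(wFlat) - 1L)]
  expect_true(all(abs(interior / mean(interior) - 1) < 0.01))

  # near-point-mass at an exact grid point
  j <- 41L
  wPoint <- discretizePrior(c(log10(grid@s[j]), log(1e-6)), grid)
  expect_gte(wPoint[j], 0.999)
})

test_that("marginal log-likelihood reduces to the documented identities", {
  grid <- tinyGrid(5L)
  # constant likelihood: marginal equals the constant for any theta
  expect_equal(marginalLoglik(c(-3, log(0.7)), rep(log(0.2), 5L), grid),
               log(0.2), tolerance = 1e-12)
  # point-mass prior picks out one grid entry
  L <- c(-2, -1, -0.5, -1.5, -3)
  expect_equal(marginalLoglik(c(log10(grid@s[3L]), log(1e-6)), L, grid),
               L[3L], tolerance = 1e-6)
  # 5-point toy grid: direct summation
  theta <- c(-3, log(1.2))
  w <- discretizePrior(theta, grid)
  expect_equal(marginalLoglik(theta, L, grid), log(sum(w * exp(L))),
               tolerance = 1e-12)
})

test_that("loss gradients match central finite differences", {
  grid <- defaultSelectionGrid()
  # constant likelihood: zero gradient
  expect_equal(lossGradient(c(-4, log(0.8)), rep(-1, 101L), grid),
               c(0, 0), tolerance = 1e-10)
  # symmetric likelihood about m: zero location gradient
  x <- log10(grid@s)
  m <- -4
  Lsym <- -(x - m)^2
  expect_lt(abs(lossGradient(c(m, log(0.6)), Lsym, grid)[1L]), 1e-8)

  set.seed(42)
  for (i in 1:20) {
    th <- c(runif(1, -7, -0.5), log(runif(1, 0.1, 2)))
    L <- rnorm(101L, -2, 1.5)
    g <- lossGradient(th, L, grid)
    fd <- vapply(1:2, function(d) {
      h <- 1e-5
      e <- numeric(2L); e[d] <- h
      (-marginalLoglik(th + e, L, grid) +
         marginalLoglik(th - e, L, grid)) / (2 * h)
    }, numeric(1L))
    expect_lt(sqrt(sum((g - fd)^2)) / max(sqrt(sum(fd^2)), 1e-8), 1e-4)
  }
})

test_that("chromosome splits follow the default partition", {
  feats <- toyFeatures(30L)
  sp <- chromosomeSplit(feats)
  byChrom <- setNames(feats$chrom, feats$gene)
  expect_true(all(byChrom[sp$validation] %in% c("2", "4", "6")))
  expect_true(all(byChrom[sp$test] %in% c("1", "3", "5")))
  expect_true("X" %in% byChrom[sp$train])
  # disjoint and exhaustive
  all3 <- c(sp$train, sp$validation, sp$test)
  expect_setequal(all3, feats$gene)
  expect_equal(anyDuplicated(all3), 0L)
  expect_error(chromosomeSplit(c(g1 = "chr7", g2 = "banana")),
               "unknown chromosome")
})

test_that("zero boosting iterations reproduce the featureless baseline", {
  grid <- tinyGrid()
  feats <- toyFeatures(30L)
  set.seed(8)
  L <- matrix(rnorm(30 * length(grid@s), -1, 0.5), 30L,
              dimnames = list(feats$gene, NULL))
  gl <- new("GeneLikelihoods", loglik = L,
            neutralLoglik = setNames(numeric(30L), feats$gene),
            nSites = setNames(integer(30L), feats$gene),
            nVariantSites = setNames(integer(30L), feats$gene),
            pMiss = 0, grid = grid)
  prior <- fitPrior(feats, gl, boostConfig(maxIterations = 0L))
  th <- predictTheta(prior, feats)
  expect_true(all(th[, 1L] == prior@theta0[1L]))
  expect_true(all(th[, 2L] == prior@theta0[2L]))
  expect_equal(prior@bestIter, 0L)
})

test_that("boosting learns informative features and is deterministic", {
  grid <- defaultSelectionGrid()
  cfg <- tinySimConfig(seed = 44L, G = 92L)
  gen <- generateGenes(cfg)
  sites <- simulateGeneSites(gen$truth, cfg)
  gl <- suppressMessages(
    geneCompositeLoglik(sites, grid, cfg$pMissTrue, cfg$demography,
                        genes = gen$features$gene))
  bc <- boostConfig(maxIterations = 200L, seed = 3L)
  fit <- fitPrior(gen$features, gl, bc)
  h <- fit@history

  # validation loss at the kept iteration beats the featureless baseline
  expect_lt(min(h$valLoss), h$valLoss[h$iter == 0L])
  # early stopping bookkeeping: best iteration attains the minimum
  expect_equal(h$valLoss[h$iter == fit@bestIter], min(h$valLoss))
  # training loss is near-monotone for the accepted iterations
  upTo <- h$trainLoss[h$iter <= fit@bestIter]
  expect_lt(max(upTo - cummin(upTo)), 0.02)
  expect_lt(upTo[length(upTo)], upTo[1L])

  # the recorded final train loss is reproduced by prediction
  thTrain <- predictTheta(fit, gen$features, iterations = max(h$iter))
  trainGenes <- gen$features$gene %in% chromosomeSplit(gen$features)$train
  reLoss <- -mean(shetboost:::.marginalLoglikVec(
    thTrain[trainGenes, , drop = FALSE],
    gl@loglik[gen$features$gene[trainGenes], , drop = FALSE], grid))
  expect_lt(abs(reLoss - h$trainLoss[nrow(h)]), 1e-6)

  # full determinism given the seed
  fit2 <- fitPrior(gen$features, gl, bc)
  expect_identical(fit@history, fit2@history)
  expect_identical(predictTheta(fit, gen$features),
                   predictTheta(fit2, gen$features))
})

test_that("feature-independent truth does not let features win (leakage)", {
  grid <- defaultSelectionGrid()
  cfg <- tinySimConfig(seed = 45L, G = 92L, nInformative = 0L,
                       effectCoefs = numeric(0L), noiseSd = 0.8)
  gen <- generateGenes(cfg)
  sites <- simulateGeneSites(gen$truth, cfg)
  gl <- suppressMessages(
    geneCompositeLoglik(sites, grid, cfg$pMissTrue, cfg$demography,
                        genes = gen$features$gene))
  fit <- fitPrior(gen$features, gl, boostConfig(maxIterations = 120L))
  h <- fit@history
  # no more than noise-level improvement over the featureless baseline,
  # with noise quantified as twice the standard error of the mean
  # per-gene validation loss under the baseline prior
  sp <- chromosomeSplit(gen$features)
  valIdx <- gen$features$gene %in% sp$validation
  perGene <- shetboost:::.marginalLoglikVec(
    matrix(fit@theta0, sum(valIdx), 2L, byrow = TRUE),
    gl@loglik[gen$features$gene[valIdx], , drop = FALSE], grid)
  noise <- 2 * sd(perGene) / sqrt(sum(valIdx))
  expect_lt(h$valLoss[h$iter == 0L] - min(h$valLoss), noise)
})

test_that("hyperparameter search ranks deterministically", {
  grid <- tinyGrid()
  feats <- toyFeatures(30L)
  set.seed(9)
  L <- matrix(rnorm(30 * length(grid@s), -1, 0.5), 30L,
              dimnames = list(feats$gene, NULL))
  gl <- new("GeneLikelihoods", loglik = L,
            neutralLoglik = setNames(numeric(30L), feats$gene),
            nSites = setNames(integer(30L), feats$gene),
            nVariantSites = setNames(integer(30L), feats$gene),
            pMiss = 0, grid = grid)
  one <- boostConfig(maxIterations = 5L)
  hs1 <- hyperparameterSearch(list(one), feats, gl)
  expect_identical(hs1$bestConfig, one)

  configs <- list(boostConfig(0.01, maxIterations = 5L),
                  boostConfig(0.04, maxIterations = 5L),
                  boostConfig(0.04, maxDepth = 4L, maxIterations = 5L))
  hs <- hyperparameterSearch(configs, feats, gl)
  expect_equal(min(hs$leaderboard$valLoss, na.rm = TRUE),
               hs$leaderboard$valLoss[hs$leaderboard$rank == 1L])
  hsB <- hyperparameterSearch(configs, feats, gl)
  expect_identical(hs$leaderboard, hsB$leaderboard)
  # tuning grids carry the documented sizes
  expect_length(fullTuningGrid(), 3L^6 * 3L)
  expect_length(categoryTuningGrid(), 16L)
})

test_that("trained priors persist to text and reload bit-identically", {
  grid <- defaultSelectionGrid()
  cfg <- tinySimConfig(seed = 46L, G = 46L)
  gen <- generateGenes(cfg)
  sites <- simulateGeneSites(gen$truth, cfg)
  gl <- suppressMessages(
    geneCompositeLoglik(sites, grid, 0.1, cfg$demography,
                        genes = gen$features$gene))
  fit <- fitPrior(gen$features, gl, boostConfig(maxIterations = 30L))
  dir <- file.path(tempdir(), "prior-store")
  saveTrainedPrior(fit, dir)
  back <- loadTrainedPrior(dir)
  expect_identical(predictTheta(back, gen$features),
                   predictTheta(fit, gen$features))
  expect_equal(back@theta0, fit@theta0)
  expect_equal(back@bestIter, fit@bestIter)
})
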