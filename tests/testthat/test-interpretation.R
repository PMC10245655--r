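# Feature interpretation: correlation pruning, percentile-sweep scores,
# curve centering, per-category models, expression subgrouping.

test_that("pruning keeps one representative per correlated group", {
  feats <- toyFeatures(40L)
  # uncorrelated noise: everything retained
  pr <- pruneFeatures(feats, seed = 1L)
  expect_setequal(pr$retained, c("f1", "f2", "f3"))

  # an exact duplicate: exactly one of the pair survives
  feats$f1copy <- feats$f1
  pr2 <- pruneFeatures(feats, seed = 1L)
  expect_equal(sum(c("f1", "f1copy") %in% pr2$retained), 1L)

  # chain A-B, B-C above threshold, A-C below: one component, one kept
  withr::with_seed(3L, {
    a <- rnorm(200)
    b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(200)
    cc <- 0.9 * b + sqrt(1 - 0.81) * rnorm(200)
  })
  expect_gt(abs(cor(a, b, method = "spearman")), 0.7)
  expect_gt(abs(cor(b, cc, method = "spearman")), 0.7)
  chain <- data.frame(gene = sprintf("g%03d", 1:200),
                      chrom = rep(c(as.character(1:22), "X"),
                                  length.out = 200L),
                      A = a, B = b, C = cc, check.names = FALSE)
  pr3 <- pruneFeatures(chain, seed = 5L)
  expect_length(pr3$retained, 1L)
  expect_length(pr3$groups[[1L]], 3L)

  # determinism given the seed
  expect_identical(pruneFeatures(chain, seed = 5L)$retained, pr3$retained)

  # zero-variance features are excluded with a warning
  chain$flat <- 1
  expect_warning(pruneFeatures(chain, seed = 1L), "zero-variance")
})

test_that("feature scores are zero for unused features and stable", {
  grid <- tinyGrid()
  feats <- toyFeatures(30L)
  set.seed(12)
  L <- matrix(rnorm(30 * length(grid@s), -1, 0.5), 30L,
              dimnames = list(feats$gene, NULL))
  gl <- new("GeneLikelihoods", loglik = L,
            neutralLoglik = setNames(numeric(30L), feats$gene),
            nSites = setNames(integer(30L), feats$gene),
            nVariantSites = setNames(integer(30L), feats$gene),
            pMiss = 0, grid = grid)
  baseline <- fitPrior(feats, gl, boostConfig(maxIterations = 0L))
  fs <- featureScore(baseline, feats, "f1")
  expect_equal(fs@score, 0)
  expect_length(fs@values, 51L)

  # permutation of gene row order leaves the score unchanged
  perm <- feats[sample(nrow(feats)), ]
  fsPerm <- featureScore(baseline, perm, "f1")
  expect_equal(fsPerm@score, fs@score)
})

test_that("an informative feature outscores pure noise", {
  grid <- defaultSelectionGrid()
  cfg <- tinySimConfig(seed = 51L, G = 184L)
  gen <- generateGenes(cfg)
  sites <- simulateGeneSites(gen$truth, cfg)
  gl <- suppressMessages(
    geneCompositeLoglik(sites, grid, cfg$pMissTrue, cfg$demography,
                        genes = gen$features$gene))
  fit <- fitPrior(gen$features, gl, boostConfig(maxIterations = 300L))
  scores <- vapply(c("informative_1", "noise_1", "noise_2", "noise_3"),
                   function(f) featureScore(fit, gen$features, f)@score,
                   numeric(1L))
  expect_gt(scores[["informative_1"]], max(scores[c("noise_1", "noise_2",
                                                    "noise_3")]))
})

test_that("curve centering symmetrizes endpoints and preserves the score", {
  grid <- tinyGrid()
  vals <- seq(0.1, 0.3, length.out = 51L)
  fs <- new("FeatureScore", feature = "f", percentiles = seq(0, 100, 2),
            values = vals, score = sd(vals),
            centered = vals - (vals[1L] + vals[51L]) / 2)
  cc <- centerCurve(fs)
  expect_equal(cc[1L], -0.1)
  expect_equal(cc[51L], 0.1)
  expect_equal(sd(cc), fs@score)
  expect_equal(centerCurve(rep(0.25, 51L)), rep(0, 51L))
})

test_that("category models bracket Baseline and All correctly", {
  grid <- defaultSelectionGrid()
  cfg <- tinySimConfig(seed = 52L, G = 92L)
  gen <- generateGenes(cfg)
  sites <- simulateGeneSites(gen$truth, cfg)
  gl <- suppressMessages(
    geneCompositeLoglik(sites, grid, cfg$pMissTrue, cfg$demography,
                        genes = gen$features$gene))
  catMap <- data.frame(
    feature = c("informative_1", "informative_2", "noise_1", "noise_2"),
    category = c("signal", "signal", "noisecat", "noisecat"))
  configs <- list(boostConfig(maxIterations = 60L))
  rep <- categoryModels(gen$features, gl, catMap, configs)
  expect_true(all(c("All", "Baseline", "signal", "noisecat")
                  %in% rep$category))
  # the informative category beats the pure-noise category on test genes
  expect_gt(rep$meanTestLoglik[rep$category == "signal"],
            rep$meanTestLoglik[rep$category == "noisecat"])
  # a category containing every feature reproduces the "All" report
  allMap <- data.frame(feature = shetboost:::.featureColumns(gen$features),
                       category = "everything")
  rep2 <- categoryModels(gen$features, gl, allMap, configs)
  expect_equal(rep2$meanTestLoglik[rep2$category == "everything"],
               rep2$meanTestLoglik[rep2$category == "All"])
  expect_error(categoryModels(gen$features, gl,
                              data.frame(feature = "nope", category = "c"),
                              configs),
               "empty")
})

test_that("expression features group by substring-matched terms", {
  feats <- c("brain_cortex_tpm", "FetalBlood_pc1", "lung_airway_mean",
             "random_feature")
  sg <- expressionSubgroups(feats)
  expect_true(all(c("Brain", "Blood", "Lung") %in% sg$category))
  expect_false("random_feature" %in%
                 sg$feature[!sg$category %in% "Development"])
  expect_equal(sort(sg$feature[sg$category == "Lung"]),
               "lung_airway_mean")
})
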