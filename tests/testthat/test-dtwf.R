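# Wright-Fisher core: stationarity, one-generation evolution, sampling
# layer, likelihood curves, and the forward Monte-Carlo oracle.

test_that("stationary distribution has the absorbing and purging limits", {
  # no mutational influx: count 0 is absorbing
  d <- stationaryDistribution(10, s = 0.3, mu = 0)
  expect_equal(d@p[1L], 1)
  expect_sums_to_one(d@p)

  # lethal heterozygotes purge all copies each generation
  d <- stationaryDistribution(100, s = 1, mu = 1e-6)
  expect_gt(d@p[1L], 0.999)

  # general validity: non-negative, sums to 1, zero mass on the fixed class
  d <- stationaryDistribution(50, s = 0.01, mu = 1e-5)
  expect_true(all(d@p >= 0))
  expect_sums_to_one(d@p)
  expect_equal(d@p[101L], 0)
})

test_that("stationary distribution matches a hand-built 3-state chain", {
  # N = 1 (2 alleles), s = 0: build the 3x3 transition matrix by hand,
  # condition on non-fixation, and power iterate independently (rate kept
  # inside the mutation-model bound)
  mu <- 8e-4
  fpp <- function(f) f + (1 - f) * mu
  Tm <- t(vapply(0:2, function(i) dbinom(0:2, 2, fpp(i / 2)), numeric(3L)))
  Tc <- Tm[1:2, 1:2]  # drop the absorbing fixed state
  v <- c(1, 0)
  for (i in 1:5000) {
    v <- as.numeric(v %*% Tc)
    v <- v / sum(v)
  }
  d <- stationaryDistribution(1, s = 0, mu = mu)
  expect_equal(d@p[1:2], v, tolerance = 1e-9)
  expect_equal(d@p[3L], 0)
})

test_that("stationary distribution is invariant under conditioned evolution", {
  for (par in list(c(0, 1e-5), c(1e-3, 1e-4), c(0.1, 1e-6))) {
    d <- stationaryDistribution(40, s = par[1L], mu = par[2L])
    e <- evolveGeneration(d, s = par[1L], mu = par[2L])
    p <- e@p
    p[length(p)] <- 0
    p <- p / sum(p)
    expect_lt(0.5 * sum(abs(p - d@p)), 1e-10)
  }
})

test_that("stationarity cap breach is an explicit error naming parameters", {
  expect_error(stationaryDistribution(30, s = 0, mu = 1e-5, capFactor = 0L),
               "did not converge.*s=0.*mu=1e-05")
})

test_that("one-generation evolution matches hand enumeration", {
  # point mass at 0 with mu = 0 stays put
  d0 <- new("FrequencyDistribution", p = c(1, rep(0, 8L)), N = 4L)
  expect_equal(evolveGeneration(d0, s = 0.7, mu = 0)@p, d0@p)

  # neutral drift martingale: expected frequency preserved
  set.seed(1)
  p <- runif(9)
  d <- new("FrequencyDistribution", p = p / sum(p), N = 4L)
  e <- evolveGeneration(d, s = 0, mu = 0)
  expect_equal(sum(e@p * 0:8) / 8, sum(d@p * 0:8) / 8, tolerance = 1e-12)

  # 2N = 4, one copy, s = 0.1, mu = 0.01: explicit enumeration
  d1 <- new("FrequencyDistribution", p = c(0, 1, 0, 0, 0), N = 2L)
  f <- 1 / 4
  fp <- f * 0.9 / (f * 0.9 + (1 - f))
  fpp <- fp + (1 - fp) * 0.01
  expect_equal(evolveGeneration(d1, s = 0.1, mu = 0.01)@p,
               dbinom(0:4, 4, fpp), tolerance = 1e-12)

  # population size change resizes the support
  expect_length(evolveGeneration(d1, s = 0, mu = 0, Nnext = 5L)@p, 11L)
})

test_that("sampling layer is a normalized binomial mixture", {
  d0 <- new("FrequencyDistribution", p = c(1, 0, 0, 0, 0), N = 2L)
  expect_equal(sampleLikelihood(d0, AN = 10, AC = 0), 1)
  expect_equal(sampleLikelihood(d0, AN = 10, AC = 3), 0)

  d <- new("FrequencyDistribution", p = c(0.4, 0.3, 0.2, 0.05, 0.05),
           N = 2L)
  # hand-computed mixture at AN = 2
  hand <- sum(d@p * dbinom(1, 2, (0:4) / 4))
  expect_equal(sampleLikelihood(d, AN = 2, AC = 1), hand)
  tot <- sum(vapply(0:2, function(a) sampleLikelihood(d, 2, a), numeric(1L)))
  expect_lt(abs(tot - 1), 1e-8)
})

test_that("site likelihood curves have the documented shapes", {
  dem <- tinyDemography()
  grid <- tinyGrid()

  # mu = 0, AC = 0: no alleles can ever arise, likelihood constant 1
  sl0 <- siteLikelihoodCurve(0, 0, 50, dem, grid)
  expect_equal(sl0@values, rep(1, length(grid@s)))
  expect_equal(sl0@neutral, 1)

  # AC = 0 with mu > 0: non-decreasing in s (absence more probable under
  # stronger selection)
  sl <- siteLikelihoodCurve(1e-4, 0, 50, dem, grid)
  expect_true(all(diff(sl@values) >= -1e-12))
  expect_true(all(sl@values >= 0 & sl@values <= 1))

  # sums to 1 over AC at every s
  AN <- 20L
  tot <- Reduce(`+`, lapply(0:AN, function(a)
    siteLikelihoodCurve(1e-4, a, AN, dem, grid)@values))
  expect_true(all(abs(tot - 1) < 1e-8))
})

test_that("likelihood curves agree with the forward Monte-Carlo oracle", {
  dem <- tinyDemography()
  grid <- tinyGrid()
  s <- grid@s[which.min(abs(grid@s - 1e-2))]
  mu <- 2e-4
  AN <- 60L
  reps <- 40000L
  ac <- monteCarloForward(s, mu, dem, AN, reps, seed = 99L)
  expect_identical(ac, monteCarloForward(s, mu, dem, AN, reps, seed = 99L))
  # implied distribution from the matrix likelihood
  pAC <- vapply(0:AN, function(a)
    siteLikelihoodCurve(mu, a, AN, dem, grid)@values[
      which.min(abs(grid@s - s))], numeric(1L))
  obs <- tabulate(ac + 1L, nbins = AN + 1L)
  keep <- which(pAC * reps >= 5)
  o <- c(obs[keep], reps - sum(obs[keep]))
  e <- c(pAC[keep], 1 - sum(pAC[keep])) * reps
  stat <- sum((o - e)^2 / e)
  expect_lt(stat, qchisq(0.999, df = length(o) - 1L))
})

test_that("forward simulation is deterministic and respects trivial limits", {
  dem <- tinyDemography()
  ac <- monteCarloForward(0, 0, dem, 30, 500, seed = 1L, init = "zero")
  expect_true(all(ac == 0L))
})

test_that("neutral present-day mean frequency matches the simulated chain", {
  dem <- tinyDemography()
  grid <- tinyGrid()
  mu <- 2e-4
  AN <- 100L
  reps <- 60000L
  ac <- monteCarloForward(0, mu, dem, AN, reps, seed = 12L)
  pAC <- vapply(0:AN, function(a)
    siteLikelihoodCurve(mu, a, AN, dem, grid)@neutral, numeric(1L))
  mMat <- sum(pAC * 0:AN)
  se <- sd(ac) / sqrt(reps)
  expect_lt(abs(mean(ac) - mMat), 5 * se + 1e-3)
})

test_that("likelihood cache is keyed by mu bin and persists to disk", {
  dem <- tinyDemography()
  grid <- tinyGrid()
  a <- siteLikelihoodCurve(1.0001e-4, 0, 30, dem, grid)
  b <- siteLikelihoodCurve(1.0004e-4, 0, 30, dem, grid)  # same 3-digit bin
  expect_identical(a@values, b@values)

  cd <- file.path(tempdir(), "likcache-test")
  x <- siteLikelihoodCurve(3e-4, 1, 30, dem, grid, cacheDir = cd)
  expect_true(length(list.files(cd)) > 0)
  clearLikelihoodCache()
  y <- siteLikelihoodCurve(3e-4, 1, 30, dem, grid, cacheDir = cd)
  expect_equal(x@values, y@values, tolerance = 1e-12)
})

test_that("demography files round-trip and validity holds", {
  dem <- demographicModel(c(NA, 7L, 3L), c(25L, 50L, 100L))
  f <- tempfile(fileext = ".tsv")
  writeDemography(dem, f)
  back <- readDemography(f)
  expect_equal(epochTable(back), epochTable(dem))
  expect_equal(presentSize(back), 100L)
  expect_error(demographicModel(c(5L, NA), c(10L, 20L)), "burn-in")
  expect_error(selectionGrid(c(0.1, 0.1)), "strictly increasing")
  expect_error(selectionGrid(c(0, 0.5)), "\\(0, 1\\]")
})
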