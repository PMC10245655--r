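# Shared small objects for the test suite. Everything is built in code;
# sizes are kept small so individual DTWF solves take milliseconds.

# tiny demography: burn-in at N = 30, then 5 generations at N = 60
tinyDemography <- function() demographicModel(c(NA, 5L), c(30L, 60L))

tinyGrid <- function(n = 21L) defaultSelectionGrid(n)

# informative tiny simulation: rates high enough that neutral sites are
# frequently polymorphic at this scale
tinySimConfig <- function(seed = 7L, G = 46L, ...) {
  args <- list(G = G, K = 6L, nInformative = 2L, effectCoefs = c(1, 0.8),
               sitesPerGene = 8L, AN = 200L,
               demography = demographicModel(c(NA, 5L), c(50L, 100L)),
               muTable = 10^seq(-5, -3.5, length.out = 6L),
               naFrac = 0.05, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}

# hand-built 12-row curation fixture (same content as the packaged one)
curationFixture <- function() {
  read.delim(system.file("extdata", "curation_variants.tsv",
                         package = "shetboost"))
}

# deterministic small feature table
toyFeatures <- function(G = 30L, seed = 5L) {
  withr::with_seed(seed, {
    data.frame(gene = sprintf("g%02d", seq_len(G)),
               chrom = rep(c(as.character(1:22), "X"), length.out = G),
               f1 = rnorm(G), f2 = rnorm(G), f3 = rnorm(G),
               check.names = FALSE)
  })
}

expect_sums_to_one <- function(w, tol = 1e-10) {
  expect_lt(abs(sum(w) - 1), tol)
}
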