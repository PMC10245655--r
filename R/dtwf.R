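#' Stationary allele-frequency distribution
#'
#' Equilibrium of the discrete-time Wright-Fisher chain with genic selection
#' (offspring weights 1, 1 - s, 1 - 2s, floored at zero) and one-way
#' wild-type to LOF mutation, conditioned on the LOF not having fixed.
#' Under one-way mutation the fixed class is absorbing, so the unconditioned
#' chain has no informative stationary law; the quasi-stationary
#' distribution conditioned on non-fixation is the equilibrium actually
#' attained by segregating-or-absent sites and is what initializes the
#' oldest (burn-in) epoch.
#'
#' Computed by power iteration over doubling horizons followed by a
#' single-generation polish; on return the conditioned one-generation update
#' moves the distribution by less than \code{tol} in total variation.
#'
#' @param N diploid population size.
#' @param s selection coefficient per LOF copy, in [0, 1].
#' @param mu per-site per-generation LOF mutation rate (< 1e-3).
#' @param tol total-variation convergence tolerance.
#' @param capFactor iteration cap, in units of 2N generations; breaching the
#'   cap is an error naming the parameters, never a silent return.
#' @return a [FrequencyDistribution-class] over counts 0..2N.
#' @examples
#' d <- stationaryDistribution(50, s = 0.1, mu = 1e-6)
#' sum(d@p)
#' @export
stationaryDistribution <- function(N, s, mu, tol = 1e-12, capFactor = 50L) {
  stopifnot(N >= 1, s >= 0, s <= 1, mu >= 0, mu < 1e-3)
  p <- as.numeric(cpp_quasi_stationary(as.integer(N), s, mu, tol,
                                       as.integer(capFactor)))
  new("FrequencyDistribution", p = p, N = as.integer(N))
}

#' Evolve an allele-frequency distribution one generation
#'
#' Selection (genic approximation of additive diploid fitness, floored at
#' zero), then one-way mutation, then binomial resampling into a population
#' of diploid size \code{Nnext}. The degenerate source state f = 1 with
#' zero allele weight is retained at f = 1.
#'
#' @param dist a [FrequencyDistribution-class]
#' @param s selection coefficient in [0, 1]
#' @param mu mutation rate
#' @param Nnext diploid size of the offspring generation (defaults to the
#'   current size)
#' @return a [FrequencyDistribution-class] over counts 0..2*Nnext
#' @export
evolveGeneration <- function(dist, s, mu, Nnext = dist@N) {
  stopifnot(is(dist, "FrequencyDistribution"), s >= 0, s <= 1)
  p <- cpp_dtwf_step(dist@p, s, mu, 2L * as.integer(Nnext))
  new("FrequencyDistribution", p = p / sum(p), N = as.integer(Nnext))
}

#' Likelihood of a sample allele count
#'
#' Probability of observing \code{AC} copies among \code{AN} sampled
#' alleles, integrating over the population allele-count distribution with
#' binomial (with-replacement) sampling. \code{AN} larger than the haploid
#' population count is permitted under this convention but flagged with a
#' message.
#'
#' @param dist a [FrequencyDistribution-class]
#' @param AN number of sampled alleles (>= 1)
#' @param AC observed allele count, 0 <= AC <= AN
#' @return probability in [0, 1]
#' @export
sampleLikelihood <- function(dist, AN, AC) {
  stopifnot(AN >= 1, AC >= 0, AC <= AN)
  twoN <- 2L * dist@N
  if (AN > twoN)
    message("AN (", AN, ") exceeds the haploid population count (", twoN,
            "); binomial sampling with replacement is used")
  sum(dist@p * dbinom(AC, AN, (0:twoN) / twoN))
}

# ---- likelihood cache -----------------------------------------------------

.likCache <- new.env(parent = emptyenv())

.muBin <- function(mu) signif(mu, 3L)

.cacheKey <- function(mu, demography, grid) {
  sprintf("%s|%s|mu%.6g", demography@hash, .gridHash(grid), .muBin(mu))
}

#' Clear the in-memory likelihood cache
#' @export
clearLikelihoodCache <- function() {
  rm(list = ls(.likCache), envir = .likCache)
  invisible(NULL)
}

# Present-day allele-count distributions for s = 0 plus every grid value
# (columns), cached by (mu bin, demography hash, grid hash). Mutation rates
# are binned to 3 significant digits for the cache key, which bounds cache
# size with negligible likelihood error. If cacheDir is given, matrices are
# also persisted as tab-delimited tables (format v1: one header row naming
# the s values).
.presentDistMatrix <- function(mu, demography, grid, tol = 1e-12,
                               capFactor = 50L, cacheDir = NULL) {
  key <- .cacheKey(mu, demography, grid)
  if (!is.null(.likCache[[key]])) return(.likCache[[key]])
  if (!is.null(cacheDir)) {
    f <- file.path(cacheDir, paste0("likcache_v1_", gsub("[|;]", "_", key),
                                    ".tsv"))
    if (file.exists(f)) {
      M <- as.matrix(read.delim(f, check.names = FALSE))
      dimnames(M) <- list(NULL, colnames(M))
      .likCache[[key]] <- M
      return(M)
    }
  }
  ep <- .epochVectors(demography)
  svals <- c(0, grid@s)
  M <- cpp_present_dists(svals, .muBin(mu), ep$durations, ep$sizes, tol,
                         as.integer(capFactor))
  colnames(M) <- format(svals, digits = 8)
  .likCache[[key]] <- M
  if (!is.null(cacheDir)) {
    dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
    f <- file.path(cacheDir, paste0("likcache_v1_", gsub("[|;]", "_", key),
                                    ".tsv"))
    write.table(M, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  M
}

#' Per-site likelihood curve over the s_het grid
#'
#' For each s on the grid (plus the neutral point s = 0): initialize at the
#' conditioned stationary distribution of the oldest epoch, evolve through
#' all later epochs, then integrate the binomial sampling layer to obtain
#' P(AC | s, mu, demography, AN). Present-day distributions are cached keyed
#' by (mu bin, demography hash, grid hash).
#'
#' @param mu per-site mutation rate
#' @param AC observed allele count
#' @param AN sampled allele number
#' @param demography a [DemographicModel-class]
#' @param grid a [SelectionGrid-class]
#' @param tol,capFactor stationarity controls, see
#'   [stationaryDistribution()]
#' @param cacheDir optional directory for a persistent likelihood cache
#' @return a [SiteLikelihood-class]
#' @examples
#' sl <- siteLikelihoodCurve(1e-7, 0, 100,
#'   demographicModel(c(NA, 5), c(30, 60)), defaultSelectionGrid(21))
#' @export
siteLikelihoodCurve <- function(mu, AC, AN, demography, grid,
                                tol = 1e-12, capFactor = 50L,
                                cacheDir = NULL) {
  stopifnot(mu >= 0, AC >= 0, AC <= AN, AN >= 1)
  M <- .presentDistMatrix(mu, demography, grid, tol, capFactor, cacheDir)
  twoN <- nrow(M) - 1L
  if (AN > twoN)
    message("AN (", AN, ") exceeds present-day 2N (", twoN,
            "); binomial sampling with replacement is used")
  w <- dbinom(AC, AN, (0:twoN) / twoN)
  lik <- as.numeric(crossprod(w, M))
  lik <- pmin(pmax(lik, 0), 1)
  new("SiteLikelihood", values = lik[-1L], neutral = lik[1L], mu = mu,
      AC = as.integer(AC), AN = as.integer(AN), grid = grid)
}

#' Forward Monte-Carlo oracle for the site likelihood
#'
#' Simulates independent forward trajectories: start sampled from the
#' conditioned stationary distribution of the oldest epoch, per-generation
#' selection, mutation and binomial resampling through the later epochs, and
#' a final binomial draw of \code{AN} alleles. Deterministic given
#' \code{seed}.
#'
#' @param s,mu selection coefficient and mutation rate
#' @param demography a [DemographicModel-class]
#' @param AN sampled allele number
#' @param reps number of replicate trajectories
#' @param seed integer seed
#' @param init \code{"stationary"} (default) starts each replicate at the
#'   conditioned stationary distribution; \code{"zero"} starts LOF-free.
#' @param tol,capFactor stationarity controls
#' @return integer vector of \code{reps} simulated allele counts
#' @export
monteCarloForward <- function(s, mu, demography, AN, reps, seed,
                              init = c("stationary", "zero"),
                              tol = 1e-12, capFactor = 50L) {
  init <- match.arg(init)
  stopifnot(reps >= 1)
  e <- demography@epochs
  withr::with_seed(as.integer(seed), {
    twoN <- 2L * e$diploidSize[1L]
    counts <- if (init == "stationary") {
      p0 <- as.numeric(cpp_quasi_stationary(e$diploidSize[1L], s, mu, tol,
                                            as.integer(capFactor)))
      sample.int(twoN + 1L, reps, replace = TRUE, prob = p0) - 1L
    } else {
      integer(reps)
    }
    if (nrow(e) > 1L) {
      for (ei in 2:nrow(e)) {
        twoNnext <- 2L * e$diploidSize[ei]
        for (g in seq_len(e$duration[ei])) {
          fpp <- cpp_freq_after(counts / twoN, s, mu)
          counts <- rbinom(reps, twoNnext, fpp)
          twoN <- twoNnext
        }
      }
    }
    rbinom(reps, AN, counts / twoN)
  })
}
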