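#' @title Core S4 classes
#' @name shetboost-classes
#' @description S4 containers for the demographic model, the s_het grid,
#'   allele-frequency distributions, per-site and per-gene likelihoods, the
#'   boosted prior, and posteriors.
NULL

#' Piecewise-constant demographic model
#'
#' Ordered epochs of diploid population sizes, oldest first. The oldest
#' epoch is the burn-in epoch (duration \code{NA}): the allele-frequency
#' distribution is initialized at the quasi-stationary distribution of that
#' epoch's size, conditioned on the LOF not having fixed. Later epochs are
#' evolved generation by generation.
#'
#' @slot epochs data.frame with columns \code{duration} (positive integer;
#'   \code{NA} for the burn-in row) and \code{diploidSize} (positive integer).
#' @slot hash canonical identifier string used as a likelihood cache key.
#' @exportClass DemographicModel
setClass("DemographicModel",
  representation(epochs = "data.frame", hash = "character"))

setValidity("DemographicModel", function(object) {
  e <- object@epochs
  if (!all(c("duration", "diploidSize") %in% names(e)))
    return("epochs must have columns 'duration' and 'diploidSize'")
  if (nrow(e) < 1L) return("at least one epoch required")
  if (any(e$diploidSize < 1L)) return("all diploid sizes must be >= 1")
  if (!is.na(e$duration[1L]))
    return("oldest epoch must be the burn-in row (duration NA)")
  if (nrow(e) > 1L && any(is.na(e$duration[-1L])))
    return("only the oldest epoch may be a burn-in row")
  if (nrow(e) > 1L && any(e$duration[-1L] < 1L))
    return("epoch durations must be >= 1")
  TRUE
})

#' Grid of s_het values
#'
#' Strictly increasing values in (0, 1] on which likelihoods, priors and
#' posteriors are discretized. The neutral point s = 0 is always carried
#' separately (it backs the misannotation mixture) and is not part of the
#' grid itself.
#'
#' @slot s strictly increasing numeric vector in (0, 1].
#' @exportClass SelectionGrid
setClass("SelectionGrid", representation(s = "numeric"))

setValidity("SelectionGrid", function(object) {
  s <- object@s
  if (length(s) < 2L) return("grid needs at least 2 points")
  if (any(s <= 0) || any(s > 1)) return("grid values must lie in (0, 1]")
  if (any(diff(s) <= 0)) return("grid values must be strictly increasing")
  TRUE
})

#' Probability distribution over population allele counts
#'
#' @slot p probability vector over counts 0..2N.
#' @slot N diploid population size the vector refers to.
#' @exportClass FrequencyDistribution
setClass("FrequencyDistribution",
  representation(p = "numeric", N = "integer"))

setValidity("FrequencyDistribution", function(object) {
  if (length(object@p) != 2L * object@N + 1L)
    return("p must have length 2N + 1")
  if (any(object@p < 0)) return("probabilities must be non-negative")
  if (abs(sum(object@p) - 1) > 1e-10) return("probabilities must sum to 1")
  TRUE
})

#' Likelihood of one observed site as a function of s_het
#'
#' @slot values P(AC | s) for each grid value of s, in [0, 1].
#' @slot neutral the same likelihood at s = 0.
#' @slot mu,AC,AN site metadata.
#' @slot grid the [SelectionGrid-class] the curve is evaluated on.
#' @exportClass SiteLikelihood
setClass("SiteLikelihood",
  representation(values = "numeric", neutral = "numeric", mu = "numeric",
                 AC = "integer", AN = "integer", grid = "SelectionGrid"))

setValidity("SiteLikelihood", function(object) {
  if (length(object@values) != length(object@grid@s))
    return("values length must match grid")
  if (any(object@values < 0) || any(object@values > 1 + 1e-12))
    return("likelihood values must lie in [0, 1]")
  TRUE
})

#' Per-gene composite log-likelihoods over the s_het grid
#'
#' Row g holds the composite log-likelihood of gene g's sites (misannotation
#' mixture applied at \code{pMiss}) at each grid value of s_het.
#'
#' @slot loglik genes x grid matrix of composite log-likelihoods.
#' @slot neutralLoglik per-gene composite log-likelihood at s = 0.
#' @slot nSites,nVariantSites per-gene site counts (variant = AC > 0).
#' @slot pMiss the misannotation probability the mixture used.
#' @slot grid the shared [SelectionGrid-class].
#' @exportClass GeneLikelihoods
setClass("GeneLikelihoods",
  representation(loglik = "matrix", neutralLoglik = "numeric",
                 nSites = "integer", nVariantSites = "integer",
                 pMiss = "numeric", grid = "SelectionGrid"))

setValidity("GeneLikelihoods", function(object) {
  if (ncol(object@loglik) != length(object@grid@s))
    return("loglik columns must match grid length")
  if (any(!is.finite(object@loglik)))
    return("composite log-likelihoods must be finite")
  TRUE
})

#' Misannotation probability estimate
#'
#' @slot pMiss probability in [0, 1] that an annotated LOF is misannotated.
#' @slot provenance \code{"fixed"} or \code{"estimated"}.
#' @slot profile data.frame (pMiss, loglik) of the profile likelihood, when
#'   estimated.
#' @slot flat TRUE when the profile was flat to within tolerance and the
#'   configured default was returned.
#' @exportClass MisannotationConfig
setClass("MisannotationConfig",
  representation(pMiss = "numeric", provenance = "character",
                 profile = "data.frame", flat = "logical"))

setValidity("MisannotationConfig", function(object) {
  if (object@pMiss < 0 || object@pMiss > 1)
    return("pMiss must lie in [0, 1]")
  TRUE
})

#' Configuration of the gradient-boosting fit
#'
#' Defaults are the selected values of the tuning grid (learning rate 0.04,
#' depth 3, subsample 0.8, min_child_weight 4, alpha 2, lambda 0, one tree
#' per iteration), with early stopping after 10 stalled validation
#' iterations and at most 1000 iterations.
#'
#' @slot learningRate,maxDepth,subsample,minChildWeight,alpha,lambda tree
#'   learner hyperparameters.
#' @slot treesPerIteration number of trees fit per parameter dimension and
#'   iteration.
#' @slot maxIterations,patience early stopping controls.
#' @slot seed integer seed; the fit is deterministic given the seed.
#' @exportClass BoostConfig
setClass("BoostConfig",
  representation(learningRate = "numeric", maxDepth = "integer",
                 subsample = "numeric", minChildWeight = "numeric",
                 alpha = "numeric", lambda = "numeric",
                 treesPerIteration = "integer", maxIterations = "integer",
                 patience = "integer", seed = "integer"))

setValidity("BoostConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@subsample <= 0 || object@subsample > 1)
    return("subsample must lie in (0, 1]")
  if (object@patience < 1L) return("patience must be >= 1")
  TRUE
})

#' Trained empirical Bayes prior
#'
#' The prior over log10 s_het for a gene is a normal density with location m
#' and scale sigma, truncated to the grid by renormalization
#' ([discretizePrior()]). theta = (m, log sigma) is predicted as theta0 plus
#' the learning-rate-scaled sum of per-iteration tree outputs.
#'
#' @slot theta0 featureless baseline parameters (m, log sigma).
#' @slot trees list (one element per boosting iteration) of lists of raw
#'   serialized xgboost boosters, one per theta dimension.
#' @slot history per-iteration train and validation losses.
#' @slot bestIter iteration with the best validation loss (0 = baseline).
#' @slot config the [BoostConfig-class] used.
#' @slot featureNames column order expected by [predictTheta()].
#' @slot grid the [SelectionGrid-class] the prior is discretized on.
#' @exportClass TrainedPrior
setClass("TrainedPrior",
  representation(theta0 = "numeric", trees = "list", history = "data.frame",
                 bestIter = "integer", config = "BoostConfig",
                 featureNames = "character", grid = "SelectionGrid"))

#' Per-gene posteriors over the s_het grid
#'
#' @slot weights genes x grid matrix of posterior weights (rows sum to 1).
#' @slot summary data.frame with columns gene, posterior_mean, lower95,
#'   upper95, regime.
#' @slot grid the shared [SelectionGrid-class].
#' @exportClass PosteriorSet
setClass("PosteriorSet",
  representation(weights = "matrix", summary = "data.frame",
                 grid = "SelectionGrid"))

setValidity("PosteriorSet", function(object) {
  w <- object@weights
  if (nrow(w) > 0) {
    if (any(w < 0)) return("posterior weights must be non-negative")
    if (any(abs(rowSums(w) - 1) > 1e-10))
      return("posterior weights must sum to 1 per gene")
  }
  TRUE
})

setMethod("show", "DemographicModel", function(object) {
  e <- object@epochs
  cat("DemographicModel with", nrow(e), "epoch(s), oldest first\n")
  cat("  burn-in diploid size:", e$diploidSize[1L], "\n")
  if (nrow(e) > 1L)
    for (i in 2:nrow(e))
      cat(sprintf("  %d generations at diploid size %d\n",
                  e$duration[i], e$diploidSize[i]))
  cat("  present-day haploid count (2N):", 2L * e$diploidSize[nrow(e)], "\n")
})

setMethod("show", "SelectionGrid", function(object) {
  cat(sprintf("SelectionGrid: %d points in [%.3g, %.3g] (log-spaced)\n",
              length(object@s), min(object@s), max(object@s)))
})

setMethod("show", "GeneLikelihoods", function(object) {
  cat(sprintf(
    "GeneLikelihoods: %d gene(s) x %d grid points (pMiss = %.3g)\n",
    nrow(object@loglik), ncol(object@loglik), object@pMiss))
})

setMethod("show", "TrainedPrior", function(object) {
  cat("TrainedPrior (normal on log10 s_het)\n")
  cat(sprintf("  baseline theta0: m = %.4f, log sigma = %.4f\n",
              object@theta0[1L], object@theta0[2L]))
  cat(sprintf("  boosting iterations kept: %d of %d recorded\n",
              object@bestIter, length(object@trees)))
})

setMethod("show", "PosteriorSet", function(object) {
  cat(sprintf("PosteriorSet: %d gene(s) x %d grid points\n",
              nrow(object@weights), ncol(object@weights)))
  if (nrow(object@summary) > 0) {
    cat("  regimes:\n")
    print(table(object@summary$regime))
  }
})
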