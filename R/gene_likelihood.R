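#' Misannotation mixture for one site
#'
#' A candidate LOF is treated as truly loss-of-function (selection s_het)
#' with probability 1 - pMiss, or misannotated and evolving neutrally (s =
#' 0) with probability pMiss, giving the mixture likelihood
#' (1 - pMiss) * L(s) + pMiss * L(0) at each grid point.
#'
#' @param siteL a [SiteLikelihood-class] (carries its neutral value)
#' @param pMiss misannotation probability in [0, 1]
#' @return numeric vector over the grid
#' @export
siteMixtureLikelihood <- function(siteL, pMiss) {
  stopifnot(is(siteL, "SiteLikelihood"))
  if (pMiss < 0 || pMiss > 1) stop("pMiss must lie in [0, 1]")
  (1 - pMiss) * siteL@values + pMiss * siteL@neutral
}

# Site likelihood matrix for a site table: rows = sites, column 1 = neutral
# (s = 0), remaining columns = grid values. Sites sharing (mu bin, AC, AN)
# are computed once.
.siteLikelihoodMatrix <- function(sites, demography, grid, tol = 1e-12,
                                  capFactor = 50L, cacheDir = NULL) {
  n <- nrow(sites)
  L <- matrix(NA_real_, n, length(grid@s) + 1L)
  key <- paste(.muBin(sites$mu), sites$AC, sites$AN, sep = "|")
  for (k in unique(key)) {
    idx <- which(key == k)
    i <- idx[1L]
    sl <- siteLikelihoodCurve(sites$mu[i], sites$AC[i], sites$AN[i],
                              demography, grid, tol, capFactor, cacheDir)
    L[idx, ] <- rep(c(sl@neutral, sl@values), each = length(idx))
  }
  L
}

#' Per-gene composite log-likelihood over the s_het grid
#'
#' Sums log mixture likelihoods over a gene's sites, assuming independence
#' across sites (composite likelihood). Invariant sites (AC = 0) contribute
#' exactly like variant sites. Likelihoods are floored at 1e-300 before the
#' log; floor hits are counted and reported via a message.
#'
#' @param sites data.frame with columns \code{gene}, \code{mu}, \code{AC},
#'   \code{AN} (one or more genes; see [readSiteTable()]).
#' @param grid a [SelectionGrid-class]
#' @param pMiss misannotation probability
#' @param demography a [DemographicModel-class]
#' @param genes optional character vector fixing the output gene order;
#'   genes without sites get an all-zero row and a warning (no LOF
#'   information).
#' @param tol,capFactor,cacheDir passed to [siteLikelihoodCurve()]
#' @return a [GeneLikelihoods-class]
#' @export
geneCompositeLoglik <- function(sites, grid, pMiss, demography,
                                genes = NULL, tol = 1e-12, capFactor = 50L,
                                cacheDir = NULL) {
  if (pMiss < 0 || pMiss > 1) stop("pMiss must lie in [0, 1]")
  genes <- genes %||% unique(sites$gene)
  nG <- length(genes)
  ns <- length(grid@s)
  if (nrow(sites) == 0L) {
    warning("no sites supplied: genes carry no LOF information")
    return(new("GeneLikelihoods",
               loglik = matrix(0, nG, ns, dimnames = list(genes, NULL)),
               neutralLoglik = setNames(numeric(nG), genes),
               nSites = setNames(integer(nG), genes),
               nVariantSites = setNames(integer(nG), genes),
               pMiss = pMiss, grid = grid))
  }
  stopifnot(all(sites$gene %in% genes))
  L <- .siteLikelihoodMatrix(sites, demography, grid, tol, capFactor,
                             cacheDir)
  mix <- (1 - pMiss) * L[, -1L, drop = FALSE] + pMiss * L[, 1L]
  lmix <- flooredLog(mix)
  lneu <- flooredLog(L[, 1L])
  hits <- attr(lmix, "floorHits") + attr(lneu, "floorHits")
  if (hits > 0)
    message(hits, " site likelihood value(s) hit the 1e-300 floor")
  gf <- factor(sites$gene, levels = genes)
  gl <- rowsum(lmix, gf)  # genes x grid; zero rows for siteless genes
  nl <- rowsum(as.numeric(lneu), gf)[, 1L]
  nSites <- as.integer(table(gf))
  if (any(nSites == 0L))
    warning(sum(nSites == 0L),
            " gene(s) have no sites and carry no LOF information")
  nVar <- as.integer(rowsum((sites$AC > 0) + 0, gf))
  new("GeneLikelihoods",
      loglik = `dimnames<-`(gl, list(genes, NULL)),
      neutralLoglik = setNames(nl, genes),
      nSites = setNames(nSites, genes),
      nVariantSites = setNames(nVar, genes),
      pMiss = pMiss, grid = grid)
}

#' Estimate the misannotation probability from the data
#'
#' Profiles the total marginal log-likelihood over a grid of pMiss values
#' under the featureless shared prior: for each candidate pMiss the
#' featureless prior parameters are re-optimized and the summed per-gene
#' marginal log-likelihood is recorded. The profile maximizer is returned.
#' Misannotation is estimated before any feature-based training
#' (two-stage).
#'
#' If the profile is flat to within \code{flatTol} (max - min of the
#' profile), the data do not identify pMiss and the configured
#' \code{default} is returned with \code{flat = TRUE}.
#'
#' @param sites site table covering at least two genes
#' @param demography a [DemographicModel-class]
#' @param grid a [SelectionGrid-class]
#' @param pGrid candidate pMiss values in [0, 1]
#' @param default pMiss returned when the profile is flat
#' @param flatTol flatness tolerance in total log-likelihood units
#' @param tol,capFactor,cacheDir passed to the likelihood machinery
#' @return a [MisannotationConfig-class]
#' @export
estimatePMiss <- function(sites, demography, grid,
                          pGrid = seq(0, 0.5, by = 0.01), default = 0.05,
                          flatTol = 1.0, tol = 1e-12, capFactor = 50L,
                          cacheDir = NULL) {
  stopifnot(length(unique(sites$gene)) >= 2L, all(pGrid >= 0),
            all(pGrid <= 1))
  genes <- unique(sites$gene)
  L <- .siteLikelihoodMatrix(sites, demography, grid, tol, capFactor,
                             cacheDir)
  gf <- factor(sites$gene, levels = genes)
  warm <- NULL
  prof <- vapply(pGrid, function(p) {
    mix <- (1 - p) * L[, -1L, drop = FALSE] + p * L[, 1L]
    gl <- rowsum(log(pmax(mix, 1e-300)), gf)
    fit <- .fitTheta0(gl, grid, warmStart = warm)
    # re-optimized featureless prior per candidate; warm-started along the
    # profile (the optimum moves continuously in pMiss)
    warm <<- fit$theta
    -fit$value
  }, numeric(1L))
  profile <- data.frame(pMiss = pGrid, loglik = prof)
  if (max(prof) - min(prof) < flatTol) {
    message("pMiss profile is flat to within ", flatTol,
            "; returning the configured default ", default)
    return(new("MisannotationConfig", pMiss = default,
               provenance = "fixed", profile = profile, flat = TRUE))
  }
  new("MisannotationConfig", pMiss = pGrid[which.max(prof)],
      provenance = "estimated", profile = profile, flat = FALSE)
}
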