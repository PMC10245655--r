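# Synthetic data with the statistical structure the estimator assumes:
# feature-driven true s_het, context-style mutation rates, forward-simulated
# allele counts, and misannotated sites evolving neutrally.

#' Simulation configuration
#'
#' Defaults define the package's standard synthetic study conditions:
#' 800 genes, 20 features of which 3 are informative, 20 sites per gene,
#' sample allele number 1000, misannotation probability 0.1, mutation rates
#' drawn from a 12-class context-style table (see \code{muTable}),
#' and the desk-scale demography of [defaultDemography()]. True log10
#' s_het is a monotone (softsign) function of the informative features plus
#' Gaussian noise (SD 0.3 on the log10 scale), clipped to the grid range.
#'
#' @param G number of genes
#' @param K number of features
#' @param nInformative number of informative features
#' @param effectIntercept intercept of the effect map (log10 scale). The
#'   default -1.5 places the bulk of true s_het two log-units above the
#'   human-scale center, matching the mutation-rate rescaling: shrinking
#'   the population ~100x while preserving the population-scaled
#'   quantities theta = 4*N*mu and 2*N*s scales both mu and s upward
#' @param effectCoefs coefficients of the softsign effect map, one per
#'   informative feature
#' @param noiseSd SD of the log10 s_het noise around the effect map
#' @param featureCor pairwise correlation among informative features
#' @param naFrac fraction of feature entries set missing
#' @param sitesPerGene integer, or a function(n) returning site counts
#' @param muTable mutation-rate classes sites draw from. The default is a
#'   12-class context-style table log-spaced over 1e-6..1e-4, the
#'   mutation-rescaled desk-scale counterpart of human LOF site rates:
#'   rates are scaled up as the demography is scaled down so that a
#'   neutral site in the top rate classes has an appreciable probability
#'   of being polymorphic, reproducing the sample-scale information
#'   structure the estimator assumes (invariant high-rate sites indicate
#'   strong selection)
#' @param pMissTrue true misannotation probability in [0, 1]
#' @param AN sample allele number
#' @param demography a [DemographicModel-class]
#' @param burninFactor burn-in length for site simulation, in units of 2N
#'   generations of the oldest epoch
#' @param seed integer seed (mandatory; all outputs are deterministic
#'   given the config)
#' @return list of class \code{SimulationConfig}
#' @export
simulationConfig <- function(G = 800L, K = 20L, nInformative = 3L,
                             effectIntercept = -1.5,
                             effectCoefs = c(1.0, 0.8, 0.6),
                             noiseSd = 0.3, featureCor = 0.3,
                             naFrac = 0.02, sitesPerGene = 20L,
                             muTable = 10^seq(-6, -4, length.out = 12L),
                             pMissTrue = 0.1, AN = 1000L,
                             demography = defaultDemography(),
                             burninFactor = 10L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(G >= 1, K >= nInformative, nInformative >= 0,
            pMissTrue >= 0, pMissTrue <= 1, AN >= 1,
            length(effectCoefs) == nInformative)
  structure(list(G = as.integer(G), K = as.integer(K),
                 nInformative = as.integer(nInformative),
                 effectIntercept = effectIntercept,
                 effectCoefs = effectCoefs, noiseSd = noiseSd,
                 featureCor = featureCor, naFrac = naFrac,
                 sitesPerGene = sitesPerGene, muTable = muTable,
                 pMissTrue = pMissTrue, AN = as.integer(AN),
                 demography = demography,
                 burninFactor = as.integer(burninFactor),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

.softsign <- function(x) x / (1 + abs(x))

#' Generate gene features and true s_het values
#'
#' Informative features share an equicorrelated Gaussian structure; true
#' log10 s_het is the softsign effect map of the informative features plus
#' noise, clipped to the grid range (a warning reports the clipped count
#' when more than 5% of genes clip). Chromosomes are assigned round-robin
#' over 1..22 and X so every chromosome split is populated. Deterministic
#' given the config seed.
#'
#' @param config a [simulationConfig()]
#' @return list(features = data.frame, truth = data.frame(gene, chrom, m,
#'   sTrue))
#' @export
generateGenes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withr::with_seed(config$seed, {
    G <- config$G; K <- config$K; nI <- config$nInformative
    z <- rnorm(G)
    rho <- config$featureCor
    X <- matrix(rnorm(G * K), G, K)
    if (nI > 0)
      X[, seq_len(nI)] <- sqrt(rho) * z +
        sqrt(1 - rho) * X[, seq_len(nI), drop = FALSE]
    colnames(X) <- c(sprintf("informative_%d", seq_len(nI)),
                     sprintf("noise_%d", seq_len(K - nI)))[seq_len(K)]
    m <- config$effectIntercept +
      if (nI > 0) as.numeric(.softsign(X[, seq_len(nI), drop = FALSE]) %*%
                               config$effectCoefs) else 0
    log10s <- m + rnorm(G, 0, config$noiseSd)
    clipped <- sum(log10s < -8 | log10s > 0)
    if (clipped > 0.05 * G)
      warning(clipped, " gene(s) clipped to the s_het grid range")
    log10s <- pmin(pmax(log10s, -8), 0)
    Xna <- X
    if (config$naFrac > 0) {
      nNA <- round(config$naFrac * length(X))
      Xna[sample(length(X), nNA)] <- NA
    }
    gene <- sprintf("gene%04d", seq_len(G))
    chrom <- rep(c(as.character(1:22), "X"), length.out = G)
    features <- data.frame(gene = gene, chrom = chrom, Xna,
                           check.names = FALSE)
    truth <- data.frame(gene = gene, chrom = chrom, m = m,
                        sTrue = 10^log10s)
    list(features = features, truth = truth)
  })
}

# vectorized selection + mutation update of per-site allele frequencies
.freqAfterVec <- function(f, s, mu) {
  w <- pmax(0, 1 - s)
  fp <- ifelse(f >= 1, 1, f * w / (f * w + (1 - f)))
  fp + (1 - fp) * mu
}

#' Simulate LOF site data for a table of genes
#'
#' Each site draws a mutation-rate class from the config table; with
#' probability \code{pMissTrue} it is misannotated and evolves neutrally
#' (s = 0), otherwise it evolves at the gene's true s_het. Sites start
#' LOF-free, burn in for \code{burninFactor * 2N} generations of the
#' oldest epoch (reaching the segregating equilibrium), evolve through the
#' later epochs, and are finally sampled binomially at \code{AN} alleles.
#' All sites are simulated in one vectorized forward pass.
#'
#' @param truth truth table from [generateGenes()] (columns gene, chrom,
#'   sTrue)
#' @param config a [simulationConfig()]
#' @return site table (gene, site_id, chrom_class, mu, AC, AN,
#'   misannotated)
#' @export
simulateGeneSites <- function(truth, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  nPer <- if (is.function(config$sitesPerGene))
    config$sitesPerGene(nrow(truth)) else
      rep(config$sitesPerGene, nrow(truth))
  withr::with_seed(config$seed + 1L, {
    gene <- rep(truth$gene, nPer)
    sGene <- rep(truth$sTrue, nPer)
    chromCls <- rep(ifelse(truth$chrom == "X", "X", "autosome"), nPer)
    n <- length(gene)
    mu <- sample(config$muTable, n, replace = TRUE)
    misann <- runif(n) < config$pMissTrue
    s <- ifelse(misann, 0, sGene)
    e <- config$demography@epochs
    twoN <- 2L * e$diploidSize[1L]
    counts <- integer(n)
    burnin <- function(cnt, sv, muv) {
      for (g in seq_len(config$burninFactor * twoN)) {
        fpp <- .freqAfterVec(cnt / twoN, sv, muv)
        cnt <- rbinom(length(cnt), twoN, fpp)
      }
      cnt
    }
    counts <- burnin(counts, s, mu)
    # condition on non-fixation at burn-in end, matching the likelihood's
    # quasi-stationary initialization: trajectories that fixed are
    # rejection-resimulated (the conditioned long-run law is the Yaglom
    # limit the matrix initialization computes)
    for (round in seq_len(100L)) {
      fixed <- which(counts >= twoN)
      if (length(fixed) == 0L) break
      if (round == 100L)
        stop("burn-in rejection did not clear fixed trajectories")
      counts[fixed] <- burnin(integer(length(fixed)), s[fixed], mu[fixed])
    }
    if (nrow(e) > 1L) {
      for (ei in 2:nrow(e)) {
        twoNnext <- 2L * e$diploidSize[ei]
        for (g in seq_len(e$duration[ei])) {
          fpp <- .freqAfterVec(counts / twoN, s, mu)
          counts <- rbinom(n, twoNnext, fpp)
          twoN <- twoNnext
        }
      }
    }
    AC <- rbinom(n, config$AN, counts / twoN)
    data.frame(gene = gene,
               site_id = paste0(gene, "_s", sequence(nPer)),
               chrom_class = chromCls, mu = mu, AC = AC,
               AN = config$AN, misannotated = misann)
  })
}

#' End-to-end parameter-recovery experiment
#'
#' Simulates genes and sites, estimates the misannotation probability,
#' computes composite likelihoods, fits the featureless and the
#' feature-based boosted priors, computes posteriors for both, and reports
#' Spearman correlations between true and estimated s_het, 95% credible
#' interval coverage, and the misannotation estimate.
#'
#' @param config a [simulationConfig()]
#' @param fitConfig a [boostConfig()] for the featured model
#' @param grid a [SelectionGrid-class]
#' @param pGrid candidate misannotation probabilities profiled
#' @param verbose print stage progress
#' @return list of class \code{RecoveryReport} with elements
#'   \code{spearmanFeatured}, \code{spearmanFeatureless},
#'   \code{coverageFeatured}, \code{coverageFeatureless},
#'   \code{pMissEstimate}, plus the fitted objects
#' @export
recoveryExperiment <- function(config, fitConfig = boostConfig(),
                               grid = defaultSelectionGrid(),
                               pGrid = seq(0, 0.5, by = 0.01),
                               verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  stage <- "generate_genes"
  out <- tryCatch({
    say("generating genes and features")
    gen <- generateGenes(config)
    stage <- "simulate_sites"
    say("simulating LOF sites")
    sites <- simulateGeneSites(gen$truth, config)
    stage <- "likelihoods"
    say("computing site likelihood curves and misannotation profile")
    pm <- suppressMessages(
      estimatePMiss(sites, config$demography, grid, pGrid = pGrid))
    gl <- suppressMessages(
      geneCompositeLoglik(sites, grid, pm@pMiss, config$demography,
                          genes = gen$features$gene))
    stage <- "fit_prior"
    say("fitting the boosted prior (pMiss = ", pm@pMiss, ")")
    split <- chromosomeSplit(gen$features)
    prior <- fitPrior(gen$features, gl, fitConfig, split)
    stage <- "posteriors"
    theta <- predictTheta(prior, gen$features)
    theta0 <- predictTheta(prior, gen$features, iterations = 0L)
    postF <- computePosterior(theta, gl)
    post0 <- computePosterior(theta0, gl)
    sTrue <- gen$truth$sTrue
    cover <- function(post) {
      sm <- post@summary[match(gen$truth$gene, post@summary$gene), ]
      mean(sm$lower95 <= sTrue & sTrue <= sm$upper95)
    }
    sp <- function(post) {
      sm <- post@summary[match(gen$truth$gene, post@summary$gene), ]
      cor(sTrue, sm$posterior_mean, method = "spearman")
    }
    structure(list(
      spearmanFeatured = sp(postF), spearmanFeatureless = sp(post0),
      coverageFeatured = cover(postF), coverageFeatureless = cover(post0),
      pMissEstimate = pm@pMiss, pMissConfig = pm,
      prior = prior, posteriorFeatured = postF,
      posteriorFeatureless = post0, likelihoods = gl,
      truth = gen$truth, features = gen$features, sites = sites,
      split = split), class = "RecoveryReport")
  }, error = function(e)
    stop("recovery experiment failed at stage '", stage, "': ",
         conditionMessage(e)))
  say(sprintf(
    "Spearman(truth, posterior mean): featured %.3f, featureless %.3f",
    out$spearmanFeatured, out$spearmanFeatureless))
  say(sprintf("95%% CI coverage (featured): %.3f; pMiss estimate: %.3f",
              out$coverageFeatured, out$pMissEstimate))
  out
}

#' @export
print.RecoveryReport <- function(x, ...) {
  cat("RecoveryReport\n")
  cat(sprintf("  genes: %d, sites: %d\n", nrow(x$truth), nrow(x$sites)))
  cat(sprintf("  Spearman(truth, posterior mean), featured:    %.3f\n",
              x$spearmanFeatured))
  cat(sprintf("  Spearman(truth, posterior mean), featureless: %.3f\n",
              x$spearmanFeatureless))
  cat(sprintf("  95%% CI coverage: featured %.3f, featureless %.3f\n",
              x$coverageFeatured, x$coverageFeatureless))
  cat(sprintf("  pMiss estimate: %.3f (%s)\n", x$pMissEstimate,
              x$pMissConfig@provenance))
  invisible(x)
}

#' Write the packaged toy fixtures
#'
#' Writes (i) the 12-row curation fixture, (ii) a 5-point-grid toy
#' prior/likelihood table, (iii) a 20-gene end-to-end mini dataset
#' (features, truth, sites), and (iv) a manifest with md5 checksums.
#' Regeneration is bit-identical (fixed seeds, fixed formatting), which is
#' asserted by the test suite against the packaged copies.
#'
#' @param path output directory
#' @return invisible character vector of written files
#' @export
makeFixtures <- function(path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) {
    write.table(d, file.path(path, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
    f
  }
  cur <- data.frame(
    chrom = c("1", "1", "1", "2", "2", "7", "7", "12", "X", "X", "5", "5"),
    pos = c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L, 900L, 1000L,
            1100L, 1200L),
    ref = c("C", "G", "A", "C", "T", "G", "C", "A", "G", "C", "T", "A"),
    alt = c("T", "A", "T", "A", "A", "T", "T", "T", "A", "T", "A", "G"),
    gene = c("GENEA", "GENEA", "GENEA", "GENEB", "GENEB", "GENEC", "GENEC",
             "GENED", "GENEE", "GENEE", "GENEF", "GENEF"),
    consequence = c("stop_gained", "missense", "splice_donor",
                    "splice_acceptor", "stop_gained", "stop_gained",
                    "synonymous", "splice_donor", "stop_gained",
                    "splice_acceptor", "stop_gained", "stop_gained"),
    lof_confidence = c("HC", "HC", "LC", "HC", "HC", "HC", "HC", "HC",
                       "HC", "HC", "HC", "HC"),
    flagged = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, TRUE, FALSE, FALSE),
    pext = c(0.9, 0.8, 0.7, 0.04, 0.95, 0.5, 0.6, NA, 0.99, 0.9, 0.2,
             0.85),
    depth = c(35, 30, 28, 40, 2, 31, 33, 25, 38, 30, 29, 27),
    segdup = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
               FALSE, FALSE, FALSE, FALSE),
    AC = c(1L, 2L, 0L, 3L, 1L, 0L, 5L, 2L, 1L, 0L, 4L, 0L),
    AN = c(1000L, 998L, NA, 1000L, 996L, NA, 1000L, 990L, 500L, NA,
           1000L, NA),
    mu = c(1e-8, 2e-8, 5e-9, 1e-7, 3e-8, 8e-8, 1e-8, 2e-8, 4e-8, 6e-8,
           1e-8, 9e-9))
  files <- wt(cur, "curation_variants.tsv")
  toy <- data.frame(
    s = c(1e-4, 1e-3, 1e-2, 1e-1, 1),
    prior = c(0.1, 0.2, 0.4, 0.2, 0.1),
    loglik = c(-2.0, -1.0, -0.5, -1.5, -3.0))
  files <- c(files, wt(toy, "toy_grid.tsv"))
  mini <- simulationConfig(G = 20L, K = 5L, nInformative = 2L,
                           effectCoefs = c(1.2, 0.8), sitesPerGene = 5L,
                           AN = 100L,
                           demography = demographicModel(c(NA, 5L),
                                                         c(30L, 60L)),
                           muTable = 10^seq(-7, -5, length.out = 6L),
                           naFrac = 0.05, seed = 42L)
  gen <- generateGenes(mini)
  sites <- simulateGeneSites(gen$truth, mini)
  fmtNum <- function(d) {
    for (j in seq_along(d)) if (is.double(d[[j]]))
      d[[j]] <- sprintf("%.17g", d[[j]])
    d
  }
  files <- c(files, wt(fmtNum(gen$features), "mini_features.tsv"),
             wt(fmtNum(gen$truth), "mini_truth.tsv"),
             wt(fmtNum(sites), "mini_sites.tsv"))
  sums <- tools::md5sum(file.path(path, files))
  manifest <- data.frame(file = files, md5 = unname(sums))
  files <- c(files, wt(manifest, "fixture_manifest.tsv"))
  invisible(files)
}
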