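#' Boosting configuration
#'
#' Defaults are the selected values of the full tuning grid; see
#' [fullTuningGrid()] for the tested values.
#'
#' @param learningRate shrinkage applied to each iteration's tree output
#' @param maxDepth maximum tree depth
#' @param subsample row subsampling ratio per tree
#' @param minChildWeight minimum leaf weight
#' @param alpha,lambda L1/L2 leaf regularization
#' @param treesPerIteration trees fit per theta dimension per iteration
#' @param maxIterations iteration cap
#' @param patience stalled validation iterations before stopping
#' @param seed integer seed (the fit is deterministic given the seed)
#' @return a [BoostConfig-class]
#' @export
boostConfig <- function(learningRate = 0.04, maxDepth = 3L,
                        subsample = 0.8, minChildWeight = 4,
                        alpha = 2, lambda = 0, treesPerIteration = 1L,
                        maxIterations = 1000L, patience = 10L, seed = 1L) {
  new("BoostConfig", learningRate = learningRate,
      maxDepth = as.integer(maxDepth), subsample = subsample,
      minChildWeight = minChildWeight, alpha = alpha, lambda = lambda,
      treesPerIteration = as.integer(treesPerIteration),
      maxIterations = as.integer(maxIterations),
      patience = as.integer(patience), seed = as.integer(seed))
}

#' Hyperparameter grids for tuning
#'
#' \code{fullTuningGrid()} is the full search grid (learning rate 2.5e-3 /
#' 0.01 / 0.04; depth 3-5; subsample 0.6 / 0.8 / 1; min_child_weight 1 / 2
#' / 4; alpha 1 / 2 / 4; lambda 0 / 1 / 2; 1 / 2 / 4 trees per iteration).
#' \code{categoryTuningGrid()} is the reduced grid used when fitting many
#' per-category models.
#'
#' @param maxIterations,patience,seed shared across all configs
#' @return list of [BoostConfig-class]
#' @export
fullTuningGrid <- function(maxIterations = 1000L, patience = 10L,
                           seed = 1L) {
  g <- expand.grid(lr = c(2.5e-3, 0.01, 0.04), depth = 3:5,
                   sub = c(0.6, 0.8, 1), mcw = c(1, 2, 4),
                   alpha = c(1, 2, 4), lambda = c(0, 1, 2),
                   trees = c(1L, 2L, 4L))
  lapply(seq_len(nrow(g)), function(i)
    boostConfig(g$lr[i], g$depth[i], g$sub[i], g$mcw[i], g$alpha[i],
                g$lambda[i], g$trees[i], maxIterations, patience, seed))
}

#' @rdname fullTuningGrid
#' @export
categoryTuningGrid <- function(maxIterations = 1000L, patience = 10L,
                               seed = 1L) {
  g <- expand.grid(lr = c(0.01, 0.04), depth = 3L, sub = c(0.8, 1),
                   mcw = c(2, 4), alpha = c(1, 2), lambda = 0,
                   trees = 1L)
  lapply(seq_len(nrow(g)), function(i)
    boostConfig(g$lr[i], g$depth[i], g$sub[i], g$mcw[i], g$alpha[i],
                g$lambda[i], g$trees[i], maxIterations, patience, seed))
}

.normChrom <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  ok <- ch %in% c(as.character(1:22), "X")
  if (any(!ok))
    stop("unknown chromosome label(s): ",
         paste(unique(chrom[!ok]), collapse = ", "))
  ch
}

#' Split genes by chromosome into train / validation / test sets
#'
#' Default split: training = chromosomes 7-22 and X, validation =
#' chromosomes 2, 4, 6, test = chromosomes 1, 3, 5. The partition is
#' disjoint and exhaustive; custom mappings are accepted.
#'
#' @param features feature data.frame with columns \code{gene} and
#'   \code{chrom}, or a named character vector of chromosome labels.
#' @param train,validation,test chromosome labels (without "chr" prefix)
#' @return list with character elements \code{train}, \code{validation},
#'   \code{test} of gene ids
#' @export
chromosomeSplit <- function(features,
                            train = c(as.character(7:22), "X"),
                            validation = c("2", "4", "6"),
                            test = c("1", "3", "5")) {
  if (is.data.frame(features)) {
    genes <- features$gene
    chrom <- features$chrom
  } else {
    genes <- names(features)
    chrom <- features
  }
  ch <- .normChrom(chrom)
  assigned <- ch %in% c(train, validation, test)
  if (any(!assigned))
    stop("chromosome(s) not covered by the split: ",
         paste(unique(ch[!assigned]), collapse = ", "))
  if (length(intersect(train, validation)) || length(intersect(train, test))
      || length(intersect(validation, test)))
    stop("split chromosome sets must be disjoint")
  list(train = genes[ch %in% train],
       validation = genes[ch %in% validation],
       test = genes[ch %in% test])
}

.featureColumns <- function(features) {
  setdiff(names(features), c("gene", "chrom"))
}

.featureMatrix <- function(features, featureNames = NULL) {
  cols <- featureNames %||% .featureColumns(features)
  X <- as.matrix(features[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- features$gene
  X
}

.xgbParams <- function(config, seed) {
  list(objective = "reg:squarederror", max_depth = config@maxDepth,
       eta = 1, subsample = config@subsample,
       min_child_weight = config@minChildWeight, alpha = config@alpha,
       lambda = config@lambda, nthread = 1, base_score = 0,
       seed = as.integer(seed %% .Machine$integer.max))
}

#' Fit the gradient-boosted empirical Bayes prior
#'
#' NGBoost-style fit: the featureless baseline theta0 is optimized first on
#' the training genes; each boosting iteration then fits
#' \code{treesPerIteration} regression trees per theta dimension to the
#' per-gene gradients of the negative marginal log-likelihood and adds the
#' learning-rate-scaled tree output to every gene's theta. Training stops
#' after \code{patience} validation iterations without improvement or at
#' \code{maxIterations}; the iteration with the best validation loss is
#' kept. Missing feature values are routed natively by the tree learner
#' (no imputation). Deterministic given \code{config@seed}.
#'
#' @param features data.frame with columns \code{gene}, \code{chrom} and
#'   numeric feature columns (NA allowed)
#' @param likelihoods a [GeneLikelihoods-class] covering every training and
#'   validation gene
#' @param config a [BoostConfig-class]
#' @param split list(train, validation, test) of gene ids; defaults to
#'   [chromosomeSplit()] of \code{features}
#' @param naturalGradient scale gradients by the inverse Fisher information
#'   of the prior family (optional refinement; default plain gradients)
#' @return a [TrainedPrior-class]
#' @export
fitPrior <- function(features, likelihoods, config = boostConfig(),
                     split = NULL, naturalGradient = FALSE) {
  stopifnot(is(likelihoods, "GeneLikelihoods"))
  split <- split %||% chromosomeSplit(features)
  if (length(split$validation) == 0L) stop("no validation genes in split")
  grid <- likelihoods@grid
  genes <- features$gene
  missingL <- setdiff(c(split$train, split$validation),
                      rownames(likelihoods@loglik))
  if (length(missingL))
    stop("genes without likelihoods: ", paste(head(missingL), collapse = ", "))
  L <- likelihoods@loglik[match(genes, rownames(likelihoods@loglik)), ,
                          drop = FALSE]
  trainIdx <- which(genes %in% split$train)
  valIdx <- which(genes %in% split$validation)
  X <- .featureMatrix(features)
  dall <- xgboost::xgb.DMatrix(X, missing = NA, nthread = 1)
  dtrain <- xgboost::xgb.DMatrix(X[trainIdx, , drop = FALSE], missing = NA,
                                 nthread = 1)

  init <- .fitTheta0(L[trainIdx, , drop = FALSE], grid)
  theta0 <- init$theta
  theta <- matrix(theta0, length(genes), 2L, byrow = TRUE)
  meanLoss <- function(idx)
    -mean(.marginalLoglikVec(theta[idx, , drop = FALSE],
                             L[idx, , drop = FALSE], grid))
  history <- data.frame(iter = 0L, trainLoss = meanLoss(trainIdx),
                        valLoss = meanLoss(valIdx))
  bestVal <- history$valLoss[1L]
  stalled <- 0L
  trees <- list()
  for (iter in seq_len(config@maxIterations)) {
    g <- .lossGradientMat(theta[trainIdx, , drop = FALSE],
                          L[trainIdx, , drop = FALSE], grid)
    if (any(!is.finite(g)))
      stop("non-finite gradient at iteration ", iter, " (gene ",
           genes[trainIdx][which(!is.finite(rowSums(g)))[1L]], ")")
    if (naturalGradient)
      g <- .naturalScale(g, theta[trainIdx, , drop = FALSE])
    iterTrees <- vector("list", 2L)
    scales <- numeric(2L)
    for (dim in 1:2) {
      # gradient targets are normalized to unit RMS before the tree fit and
      # the scale multiplied back into the update: the leaf regularization
      # (alpha, min_child_weight) then acts relative to the signal scale
      # rather than to the absolute gradient magnitude, which varies by
      # orders of magnitude with the informativeness of the LOF data
      target <- -g[, dim]
      sc <- sqrt(mean(target^2))
      scales[dim] <- sc
      if (sc == 0) next
      xgboost::setinfo(dtrain, "label", target / sc)
      bst <- xgboost::xgb.train(
        params = .xgbParams(config, config@seed + 2L * iter + dim),
        data = dtrain, nrounds = config@treesPerIteration, verbose = 0)
      pred <- predict(bst, dall)
      theta[, dim] <- theta[, dim] + config@learningRate * sc * pred
      iterTrees[[dim]] <- xgboost::xgb.save.raw(bst)
    }
    # keep per-gene priors inside the family's identifiable box (same
    # bounds as the featureless fit)
    theta[, 1L] <- pmin(pmax(theta[, 1L], log10(grid@s[1L])),
                        log10(grid@s[length(grid@s)]))
    theta[, 2L] <- pmin(pmax(theta[, 2L], log(0.05)), log(3))
    trees[[iter]] <- list(boosters = iterTrees, scales = scales)
    vl <- meanLoss(valIdx)
    history <- rbind(history,
                     data.frame(iter = iter, trainLoss = meanLoss(trainIdx),
                                valLoss = vl))
    if (vl < bestVal) {
      bestVal <- vl
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
    }
    if (stalled >= config@patience) break
    if (!is.finite(vl)) stop("non-finite validation loss at iteration ", iter)
  }
  bestIter <- history$iter[which.min(history$valLoss)]
  new("TrainedPrior", theta0 = theta0, trees = trees, history = history,
      bestIter = as.integer(bestIter), config = config,
      featureNames = colnames(X), grid = grid)
}

#' Predict per-gene prior parameters from features
#'
#' theta(gene) = theta0 plus the learning-rate-scaled sum of tree outputs
#' over the first \code{iterations} boosting iterations (default: the
#' iteration with the best validation loss; 0 gives the featureless
#' baseline for every gene).
#'
#' @param prior a [TrainedPrior-class]
#' @param features feature data.frame (same columns as used in the fit)
#' @param iterations number of boosting iterations to apply
#' @return genes x 2 matrix of (m, log sigma)
#' @export
predictTheta <- function(prior, features, iterations = prior@bestIter) {
  X <- .featureMatrix(features, prior@featureNames)
  theta <- matrix(prior@theta0, nrow(X), 2L, byrow = TRUE,
                  dimnames = list(rownames(X), c("m", "logsigma")))
  if (iterations == 0L || length(prior@trees) == 0L) return(theta)
  dm <- xgboost::xgb.DMatrix(X, missing = NA, nthread = 1)
  for (iter in seq_len(min(iterations, length(prior@trees)))) {
    it <- prior@trees[[iter]]
    for (dim in 1:2) {
      if (it$scales[dim] == 0) next
      bst <- xgboost::xgb.load.raw(it$boosters[[dim]])
      theta[, dim] <- theta[, dim] +
        prior@config@learningRate * it$scales[dim] * predict(bst, dm)
    }
  }
  theta
}

#' Mean of the learned prior on the natural s_het scale
#'
#' @param prior a [TrainedPrior-class]
#' @param features feature data.frame
#' @param iterations boosting iterations to apply (default best)
#' @return named numeric vector of per-gene prior mean s_het
#' @export
priorMeanShet <- function(prior, features, iterations = prior@bestIter) {
  theta <- predictTheta(prior, features, iterations)
  s <- prior@grid@s
  apply(theta, 1L, function(th) sum(discretizePrior(th, prior@grid) * s))
}

#' Grid search over boosting configurations
#'
#' Trains every configuration, ranks by validation loss (ties broken by
#' fewer iterations, then config order), and returns the best
#' configuration, its fit, and the full leaderboard. Configurations that
#' fail to train are recorded and skipped.
#'
#' @param configs list of [BoostConfig-class] (e.g. [fullTuningGrid()])
#' @param features,likelihoods,split,naturalGradient as in [fitPrior()]
#' @return list(bestConfig, bestFit, leaderboard)
#' @export
hyperparameterSearch <- function(configs, features, likelihoods,
                                 split = NULL, naturalGradient = FALSE) {
  stopifnot(length(configs) >= 1L)
  split <- split %||% chromosomeSplit(features)
  rows <- vector("list", length(configs))
  fits <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    fit <- tryCatch(
      fitPrior(features, likelihoods, configs[[i]], split, naturalGradient),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(config = i, valLoss = NA_real_,
                              bestIter = NA_integer_,
                              error = conditionMessage(fit))
      next
    }
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      config = i,
      valLoss = fit@history$valLoss[fit@history$iter == fit@bestIter],
      bestIter = fit@bestIter, error = NA_character_)
  }
  lb <- do.call(rbind, rows)
  ok <- which(!is.na(lb$valLoss))
  if (length(ok) == 0L) stop("every configuration failed to train")
  ord <- ok[order(lb$valLoss[ok], lb$bestIter[ok], lb$config[ok])]
  best <- ord[1L]
  lb$rank <- NA_integer_
  lb$rank[ord] <- seq_along(ord)
  list(bestConfig = configs[[best]], bestFit = fits[[best]],
       leaderboard = lb)
}

#' Save / load a trained prior
#'
#' Persists the ensemble, config and history as a versioned directory of
#' text files; reloading reproduces predictions bit-identically.
#'
#' @param prior a [TrainedPrior-class]
#' @param dir directory path
#' @name priorPersistence
#' @export
saveTrainedPrior <- function(prior, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- prior@config
  meta <- c(
    format_version = "1", m0 = sprintf("%.17g", prior@theta0[1L]),
    logsigma0 = sprintf("%.17g", prior@theta0[2L]),
    bestIter = prior@bestIter, nIter = length(prior@trees),
    learningRate = sprintf("%.17g", cfg@learningRate),
    maxDepth = cfg@maxDepth, subsample = sprintf("%.17g", cfg@subsample),
    minChildWeight = sprintf("%.17g", cfg@minChildWeight),
    alpha = sprintf("%.17g", cfg@alpha), lambda = sprintf("%.17g", cfg@lambda),
    treesPerIteration = cfg@treesPerIteration,
    maxIterations = cfg@maxIterations, patience = cfg@patience,
    seed = cfg@seed,
    gridN = length(prior@grid@s),
    gridLower = sprintf("%.17g", prior@grid@s[1L]),
    gridUpper = sprintf("%.17g", prior@grid@s[length(prior@grid@s)]))
  write.table(data.frame(key = names(meta), value = unname(meta)),
              file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(prior@featureNames, file.path(dir, "features.txt"))
  write.table(prior@history, file.path(dir, "history.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  scl <- t(vapply(prior@trees, function(it) it$scales, numeric(2L)))
  write.table(data.frame(iter = seq_len(nrow(scl)),
                         scale1 = sprintf("%.17g", scl[, 1L]),
                         scale2 = sprintf("%.17g", scl[, 2L])),
              file.path(dir, "scales.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (iter in seq_along(prior@trees))
    for (dim in 1:2)
      if (prior@trees[[iter]]$scales[dim] > 0)
        writeLines(.rawToHex(prior@trees[[iter]]$boosters[[dim]]),
                   file.path(dir, sprintf("tree_%04d_%d.hex", iter, dim)))
  invisible(dir)
}

#' @rdname priorPersistence
#' @export
loadTrainedPrior <- function(dir) {
  meta <- read.delim(file.path(dir, "meta.tsv"), colClasses = "character")
  mv <- setNames(meta$value, meta$key)
  num <- function(k) as.numeric(mv[[k]])
  int <- function(k) as.integer(mv[[k]])
  cfg <- boostConfig(num("learningRate"), int("maxDepth"), num("subsample"),
                     num("minChildWeight"), num("alpha"), num("lambda"),
                     int("treesPerIteration"), int("maxIterations"),
                     int("patience"), int("seed"))
  grid <- defaultSelectionGrid(int("gridN"), num("gridLower"),
                               num("gridUpper"))
  nIter <- int("nIter")
  scl <- if (nIter > 0)
    read.delim(file.path(dir, "scales.tsv")) else NULL
  trees <- lapply(seq_len(nIter), function(iter) {
    scales <- c(scl$scale1[iter], scl$scale2[iter])
    boosters <- lapply(1:2, function(dim) {
      if (scales[dim] == 0) return(NULL)
      .hexToRaw(readLines(file.path(dir,
                                    sprintf("tree_%04d_%d.hex", iter, dim))))
    })
    list(boosters = boosters, scales = scales)
  })
  new("TrainedPrior",
      theta0 = setNames(c(num("m0"), num("logsigma0")), c("m", "logsigma")),
      trees = trees,
      history = read.delim(file.path(dir, "history.tsv")),
      bestIter = int("bestIter"), config = cfg,
      featureNames = readLines(file.path(dir, "features.txt")), grid = grid)
}
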