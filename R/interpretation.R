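# Feature interpretation: correlation pruning, percentile-sweep feature
# scores, curve centering, and per-category models.

#' Percentile-sweep score of a single feature
#'
#' @slot feature feature name.
#' @slot percentiles the swept percentiles (0, 2, ..., 98, 100).
#' @slot values the 51 averaged prior-mean s_het predictions, one per
#'   percentile.
#' @slot score sample standard deviation of the 51 values.
#' @slot centered values minus (first + last)/2.
#' @exportClass FeatureScore
setClass("FeatureScore",
  representation(feature = "character", percentiles = "numeric",
                 values = "numeric", score = "numeric",
                 centered = "numeric"))

setMethod("show", "FeatureScore", function(object) {
  cat(sprintf("FeatureScore '%s': score = %.4g (%d sweep points)\n",
              object@feature, object@score, length(object@values)))
})

#' Prune correlated features
#'
#' Builds the graph whose edges connect feature pairs with absolute
#' Spearman correlation above \code{threshold} (pairwise-complete over
#' non-missing genes); connected components are the correlated groups and
#' one seeded-random member is retained per group. Zero-variance features
#' are excluded with a warning before correlation.
#'
#' @param features feature data.frame (gene, chrom, numeric columns)
#' @param threshold absolute Spearman correlation threshold
#' @param seed integer seed for the random representative choice
#' @return list(retained = character, groups = named list of components)
#' @export
pruneFeatures <- function(features, threshold = 0.7, seed = 1L) {
  X <- .featureMatrix(features)
  v <- apply(X, 2L, function(x) stats::var(x, na.rm = TRUE))
  zero <- !is.finite(v) | v == 0
  if (any(zero)) {
    warning("excluding zero-variance feature(s): ",
            paste(colnames(X)[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
  }
  rho <- suppressWarnings(
    cor(X, method = "spearman", use = "pairwise.complete.obs"))
  adj <- abs(rho) > threshold
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  groups <- split(colnames(X), comp$membership)
  retained <- withr::with_seed(as.integer(seed), vapply(groups, function(gr)
    if (length(gr) == 1L) gr else sample(gr, 1L), character(1L)))
  list(retained = unname(retained), groups = unname(groups))
}

#' Percentile-sweep feature score
#'
#' Fixes one feature to each of the 0th, 2nd, ..., 98th, 100th percentiles
#' of its observed distribution (linear interpolation over non-missing
#' values), sets that value for every gene, predicts each gene's prior
#' mean s_het, and averages over genes. The score is the sample standard
#' deviation of the 51 averages: a feature the trees never split on scores
#' exactly 0.
#'
#' @param prior a [TrainedPrior-class]
#' @param features feature data.frame
#' @param feature feature name to sweep
#' @return a [FeatureScore-class]
#' @export
featureScore <- function(prior, features, feature) {
  stopifnot(feature %in% prior@featureNames)
  x <- features[[feature]]
  if (all(is.na(x))) stop("feature '", feature, "' is all-missing")
  pct <- seq(0, 100, by = 2)
  vals <- quantile(x, pct / 100, na.rm = TRUE, names = FALSE, type = 7)
  sweep <- vapply(vals, function(v) {
    mod <- features
    mod[[feature]] <- v
    mean(priorMeanShet(prior, mod))
  }, numeric(1L))
  new("FeatureScore", feature = feature, percentiles = pct,
      values = sweep, score = sd(sweep),
      centered = sweep - (sweep[1L] + sweep[51L]) / 2)
}

#' Center a feature sweep curve
#'
#' Subtracts (value at the 0th percentile + value at the 100th
#' percentile)/2 from each of the 51 sweep values, so the endpoints become
#' -d/2 and +d/2. Centering is a translation and preserves the SD-based
#' score.
#'
#' @param fs a [FeatureScore-class] or a numeric 51-vector
#' @return centered numeric 51-vector
#' @export
centerCurve <- function(fs) {
  v <- if (is(fs, "FeatureScore")) fs@values else fs
  stopifnot(length(v) == 51L)
  v - (v[1L] + v[51L]) / 2
}

#' Per-category feature models
#'
#' Trains one model per feature category (tuning each over the reduced
#' hyperparameter grid) and reports the mean per-gene marginal
#' log-likelihood on the test genes. The report always includes "All"
#' (every feature) and "Baseline" (no features: the featureless shared
#' prior).
#'
#' @param features feature data.frame
#' @param likelihoods a [GeneLikelihoods-class]
#' @param categoryMap data.frame(feature, category); a feature may appear
#'   under several categories
#' @param configs list of [BoostConfig-class] to tune over
#' @param split list(train, validation, test); default [chromosomeSplit()]
#' @return data.frame(category, nFeatures, meanTestLoglik)
#' @export
categoryModels <- function(features, likelihoods, categoryMap,
                           configs = categoryTuningGrid(), split = NULL) {
  split <- split %||% chromosomeSplit(features)
  if (length(split$test) == 0L) stop("no test genes in split")
  grid <- likelihoods@grid
  testGenes <- intersect(split$test, rownames(likelihoods@loglik))
  Ltest <- likelihoods@loglik[testGenes, , drop = FALSE]
  trainL <- likelihoods@loglik[
    intersect(split$train, rownames(likelihoods@loglik)), , drop = FALSE]
  theta0 <- .fitTheta0(trainL, grid)$theta
  baseLoglik <- mean(.marginalLoglikVec(
    matrix(theta0, nrow(Ltest), 2L, byrow = TRUE), Ltest, grid))
  evalCategory <- function(feats) {
    sub <- features[, c("gene", "chrom", feats), drop = FALSE]
    hs <- hyperparameterSearch(configs, sub, likelihoods, split)
    theta <- predictTheta(hs$bestFit,
                          sub[match(testGenes, sub$gene), , drop = FALSE])
    mean(.marginalLoglikVec(theta, Ltest, grid))
  }
  cats <- unique(categoryMap$category)
  rows <- lapply(cats, function(cat) {
    feats <- intersect(categoryMap$feature[categoryMap$category == cat],
                       .featureColumns(features))
    if (length(feats) == 0L) stop("category '", cat, "' is empty")
    data.frame(category = cat, nFeatures = length(feats),
               meanTestLoglik = evalCategory(feats))
  })
  allFeats <- .featureColumns(features)
  out <- rbind(
    do.call(rbind, rows),
    data.frame(category = "All", nFeatures = length(allFeats),
               meanTestLoglik = evalCategory(allFeats)),
    data.frame(category = "Baseline", nFeatures = 0L,
               meanTestLoglik = baseLoglik))
  out[order(-out$meanTestLoglik), ]
}

#' Group expression features by substring-matched terms
#'
#' Assigns expression feature names to tissue / cell-type / developmental
#' subgroups by case-insensitive substring match against a term table
#' (columns category, terms with comma-separated substrings). The packaged
#' default table is editable configuration
#' (\code{system.file("extdata", "expression_terms.tsv", package =
#' "shetboost")}).
#'
#' @param featureNames character vector of expression feature names
#' @param termTable data.frame(category, terms); default packaged table
#' @return data.frame(feature, category) suitable for [categoryModels()]
#' @export
expressionSubgroups <- function(featureNames, termTable = NULL) {
  if (is.null(termTable))
    termTable <- read.delim(system.file("extdata", "expression_terms.tsv",
                                        package = "shetboost"))
  rows <- lapply(seq_len(nrow(termTable)), function(i) {
    terms <- trimws(strsplit(termTable$terms[i], ",")[[1L]])
    hit <- Reduce(`|`, lapply(terms, function(tm)
      grepl(tm, featureNames, ignore.case = TRUE)))
    if (!any(hit)) return(NULL)
    data.frame(feature = featureNames[hit],
               category = termTable$category[i])
  })
  do.call(rbind, rows)
}
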