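# Reference constraint metrics: observed/expected Poisson upper bound
# (LOEUF-style), threshold classifiers, matched-background enrichment.

#' Upper bound of the observed/expected confidence interval
#'
#' The LOEUF-style statistic: the upper end of the equal-tailed
#' \code{level} confidence interval for the ratio of observed to expected
#' unique LOFs under a Poisson model. Solves P(Poisson(lambda) <= observed)
#' = (1 - level)/2 by root finding to 1e-9 and returns lambda / expected.
#' Strictly increasing in observed and strictly decreasing in expected;
#' for observed = 0 it reduces to -log((1 - level)/2) / expected.
#'
#' @param observed non-negative integer count(s) of observed unique LOFs
#' @param expected positive expected unique LOFs (vectorized with observed)
#' @param level confidence level in (0, 1); default 0.90
#' @return numeric upper bound(s) of the obs/exp ratio
#' @examples
#' oeUpperBound(3, 139)   # ~0.06
#' oeUpperBound(0, 3.4)   # ~0.88
#' @export
oeUpperBound <- function(observed, expected, level = 0.90) {
  stopifnot(all(observed >= 0), all(expected > 0), level > 0, level < 1)
  target <- (1 - level) / 2
  one <- function(obs, ex) {
    f <- function(lambda) ppois(obs, lambda) - target
    hi <- max(10, 5 * (obs + 10))
    while (f(hi) > 0) hi <- hi * 2
    uniroot(f, c(1e-12, hi), tol = 1e-9)$root / ex
  }
  mapply(one, observed, expected)
}

#' Label genes as constrained / unconstrained by a threshold rule
#'
#' Supported rules: \code{"loeuf<c"} (constrained below the cutoff),
#' \code{"shet>c"} (constrained above the cutoff), \code{"top-decile"}
#' (highest-scoring 10% constrained) and \code{"bottom-decile"}
#' (lowest-scoring 10% constrained). Decile boundaries are taken by rank
#' with ties broken by gene id.
#'
#' @param scores named numeric vector (names = gene ids)
#' @param rule rule string
#' @return named logical vector: TRUE = constrained
#' @examples
#' thresholdClassify(c(A = 0.2, B = 0.5), "loeuf<0.35")
#' @export
thresholdClassify <- function(scores, rule) {
  if (!is.numeric(scores) || anyNA(scores)) stop("scores must be numeric")
  n <- length(scores)
  ids <- names(scores) %||% as.character(seq_len(n))
  if (grepl("^loeuf<", rule)) {
    out <- scores < as.numeric(sub("^loeuf<", "", rule))
  } else if (grepl("^shet>", rule)) {
    out <- scores > as.numeric(sub("^shet>", "", rule))
  } else if (rule %in% c("top-decile", "bottom-decile")) {
    k <- floor(n / 10)
    ord <- order(if (rule == "top-decile") -scores else scores, ids)
    out <- rep(FALSE, n)
    out[ord[seq_len(k)]] <- TRUE
  } else {
    stop("unknown rule: ", rule)
  }
  setNames(out, ids)
}

#' Enrichment of constrained genes in a gene set over a matched background
#'
#' Computes (fraction of set genes under constraint) / (fraction of
#' background genes under constraint), where the background is resampled
#' from all genes to match the set's distribution of the matching
#' covariate (by default the expected number of unique LOFs) using
#' stratified sampling over covariate quantile bins. Depletion is the same
#' ratio computed on the complement labels.
#'
#' @param setGenes character vector of member gene ids
#' @param covariate named numeric vector over all genes (matching variable)
#' @param constrained named logical vector over all genes
#' @param nResamples number of background resamples
#' @param seed integer seed
#' @param nBins number of covariate quantile bins
#' @param mode \code{"enrichment"} (constrained) or \code{"depletion"}
#'   (not constrained)
#' @return list(ratio, lower, upper, setFraction, backgroundFraction)
#' @export
matchedEnrichment <- function(setGenes, covariate, constrained,
                              nResamples = 200L, seed = 1L, nBins = 10L,
                              mode = c("enrichment", "depletion")) {
  mode <- match.arg(mode)
  genes <- names(covariate)
  stopifnot(!is.null(genes), all(setGenes %in% genes),
            setequal(genes, names(constrained)))
  lab <- constrained[genes]
  if (mode == "depletion") lab <- !lab
  breaks <- unique(quantile(covariate, seq(0, 1, length.out = nBins + 1L),
                            na.rm = TRUE))
  bin <- cut(covariate, breaks, include.lowest = TRUE)
  setBin <- bin[match(setGenes, genes)]
  setCounts <- table(setBin)
  byBin <- split(seq_along(genes), bin)
  empty <- names(setCounts)[setCounts > 0 &
                              !(names(setCounts) %in% names(byBin))]
  if (length(empty))
    stop("no candidate background genes in stratum ", empty[1L])
  setFrac <- mean(lab[match(setGenes, genes)])
  bgFracs <- withr::with_seed(as.integer(seed),
    vapply(seq_len(nResamples), function(r) {
      idx <- unlist(lapply(names(setCounts)[setCounts > 0], function(b)
        sample(byBin[[b]], setCounts[[b]], replace = TRUE)))
      mean(lab[idx])
    }, numeric(1L)))
  ratios <- setFrac / bgFracs
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0L)
    stop("background fraction was zero in every resample")
  list(ratio = setFrac / mean(bgFracs),
       lower = unname(quantile(ratios, 0.025)),
       upper = unname(quantile(ratios, 0.975)),
       setFraction = setFrac, backgroundFraction = mean(bgFracs))
}
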