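#' Selection regime boundaries
#'
#' s_het below 1e-4 is nearly neutral (drift-dominated), 1e-4 to 1e-3 weak
#' selection, 1e-3 to 1e-1 strong selection, and above 1e-1 extreme
#' selection. Boundary convention: 1e-4 belongs to weak, 1e-3 to strong and
#' 1e-1 to extreme.
#'
#' @export
regimeThresholds <- function() c(1e-4, 1e-3, 1e-1)

.REGIMES <- c("nearly neutral", "weak", "strong", "extreme")

#' Classify s_het values into selection regimes
#'
#' @param s numeric vector of s_het values in (0, 1]
#' @param thresholds strictly increasing boundaries (default
#'   [regimeThresholds()])
#' @return factor with levels nearly neutral / weak / strong / extreme
#' @examples
#' classifyRegime(c(1e-5, 5e-4, 0.01, 0.2))
#' @export
classifyRegime <- function(s, thresholds = regimeThresholds()) {
  stopifnot(all(diff(thresholds) > 0), length(thresholds) == 3L)
  if (any(s <= 0 | s > 1)) stop("s_het must lie in (0, 1]")
  idx <- 1L + (s >= thresholds[1L]) + (s >= thresholds[2L]) +
    (s >= thresholds[3L])
  factor(.REGIMES[idx], levels = .REGIMES)
}

# equal-tailed quantile from discrete weights on the grid: smallest grid
# value whose cumulative weight reaches q (jumps are vertical, so a
# point-mass posterior yields a zero-width interval)
.gridQuantile <- function(w, s, q) {
  cw <- cumsum(w)
  vapply(q, function(qi) s[which(cw >= qi - 1e-12)[1L]], numeric(1L))
}

.summarizeWeights <- function(w, s) {
  c(mean = sum(w * s), .gridQuantile(w, s, c(0.025, 0.975)))
}

#' Compute per-gene posteriors over s_het
#'
#' Posterior weights are proportional to the discretized prior times the
#' exponentiated composite log-likelihood, normalized stably per gene.
#'
#' @param theta prior parameters: a length-2 vector (shared prior) or a
#'   genes x 2 matrix aligned with \code{likelihoods} rows
#' @param likelihoods a [GeneLikelihoods-class]
#' @return a [PosteriorSet-class]
#' @export
computePosterior <- function(theta, likelihoods) {
  stopifnot(is(likelihoods, "GeneLikelihoods"))
  grid <- likelihoods@grid
  L <- likelihoods@loglik
  G <- nrow(L)
  thetaMat <- if (is.matrix(theta)) theta else
    matrix(theta, G, 2L, byrow = TRUE)
  stopifnot(nrow(thetaMat) == G)
  lw <- .logPriorWeights(thetaMat, grid) + L
  mx <- apply(lw, 1L, max)
  if (any(!is.finite(mx)))
    stop("all-zero unnormalized posterior for gene(s): ",
         paste(rownames(L)[!is.finite(mx)], collapse = ", "))
  W <- exp(lw - mx)
  W <- W / rowSums(W)
  s <- grid@s
  sm <- t(apply(W, 1L, .summarizeWeights, s = s))
  summary <- data.frame(
    gene = rownames(L) %||% as.character(seq_len(G)),
    posterior_mean = sm[, 1L], lower95 = sm[, 2L], upper95 = sm[, 3L],
    regime = as.character(classifyRegime(sm[, 1L])),
    row.names = NULL)
  rownames(W) <- summary$gene
  new("PosteriorSet", weights = W, summary = summary, grid = grid)
}

#' Posterior summaries
#'
#' Posterior mean on the natural s_het scale and the equal-tailed 95%
#' credible interval taken from the cumulative posterior weights on the
#' grid.
#'
#' @param posterior a [PosteriorSet-class], or a numeric weight vector
#' @param grid required when \code{posterior} is a numeric vector
#' @return data.frame gene / posterior_mean / lower95 / upper95 / regime
#' @export
summarizePosterior <- function(posterior, grid = NULL) {
  if (is(posterior, "PosteriorSet")) return(posterior@summary)
  stopifnot(!is.null(grid), length(posterior) == length(grid@s))
  sm <- .summarizeWeights(posterior / sum(posterior), grid@s)
  data.frame(posterior_mean = sm[1L], lower95 = sm[2L], upper95 = sm[3L],
             regime = as.character(classifyRegime(sm[1L])),
             row.names = NULL)
}

#' Posterior weight matrix
#' @param posterior a [PosteriorSet-class]
#' @export
posteriorWeights <- function(posterior) posterior@weights

#' Average the posterior densities of a gene set
#'
#' Unweighted mean of the member genes' posterior weight vectors; the
#' result sums to 1 and represents the distribution of s_het across the
#' set.
#'
#' @param posterior a [PosteriorSet-class]
#' @param genes character vector of member genes (default: all)
#' @return numeric density over the grid
#' @export
geneSetDensity <- function(posterior, genes = NULL) {
  W <- posterior@weights
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(W))
    if (length(miss)) stop("genes not in posterior set: ",
                           paste(miss, collapse = ", "))
    W <- W[genes, , drop = FALSE]
  }
  if (nrow(W) == 0L) stop("empty gene set")
  colMeans(W)
}

#' Write posterior results
#'
#' Emits \code{<prefix>_summary.tsv} (gene, posterior_mean, lower95,
#' upper95, regime) and \code{<prefix>_density.tsv} (genes x grid weight
#' matrix; header row carries the grid s values in order). Values are
#' written with 17 significant digits so a round-trip read reproduces them
#' exactly.
#'
#' @param posterior a [PosteriorSet-class]
#' @param prefix output path prefix
#' @return invisible character vector of the two file paths
#' @export
writeResults <- function(posterior, prefix) {
  sumFile <- paste0(prefix, "_summary.tsv")
  denFile <- paste0(prefix, "_density.tsv")
  sm <- posterior@summary
  if (nrow(sm) == 0L)
    warning("empty posterior set: writing header-only files")
  fmt <- function(x) sprintf("%.17g", x)
  out <- data.frame(gene = sm$gene, posterior_mean = fmt(sm$posterior_mean),
                    lower95 = fmt(sm$lower95), upper95 = fmt(sm$upper95),
                    regime = sm$regime)
  if (nrow(sm) == 0L)
    out <- data.frame(gene = character(), posterior_mean = character(),
                      lower95 = character(), upper95 = character(),
                      regime = character())
  write.table(out, sumFile, sep = "\t", quote = FALSE, row.names = FALSE)
  W <- posterior@weights
  den <- data.frame(gene = rownames(W) %||% character(),
                    matrix(fmt(W), nrow(W), ncol(W)))
  names(den) <- c("gene", fmt(posterior@grid@s))
  write.table(den, denFile, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(c(sumFile, denFile))
}

#' Read back posterior results written by [writeResults()]
#'
#' @param prefix the prefix passed to [writeResults()]
#' @return list(summary, weights, s)
#' @export
readResults <- function(prefix) {
  sm <- read.delim(paste0(prefix, "_summary.tsv"))
  den <- read.delim(paste0(prefix, "_density.tsv"), check.names = FALSE)
  W <- as.matrix(den[, -1L, drop = FALSE])
  rownames(W) <- den$gene
  list(summary = sm, weights = W, s = as.numeric(colnames(den)[-1L]))
}
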