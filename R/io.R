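# Tab-delimited readers/writers for the pipeline's table formats.

#' Read a site table
#'
#' Tab-delimited with columns \code{gene}, \code{site_id},
#' \code{chrom_class} (autosome|X), \code{mu}, \code{AC}, \code{AN}.
#' Invariant sites are rows with AC = 0.
#'
#' @param path file path
#' @return data.frame
#' @export
readSiteTable <- function(path) {
  d <- read.delim(path)
  need <- c("gene", "site_id", "chrom_class", "mu", "AC", "AN")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("site table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.na(d$AN) & d$AC > d$AN)
  if (length(bad)) stop("AC > AN at row(s): ", paste(head(bad), collapse = ", "))
  d
}

#' @rdname readSiteTable
#' @param sites site table
#' @export
writeSiteTable <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene feature matrix
#'
#' Tab-delimited; first columns \code{gene} and \code{chrom}, remaining
#' columns numeric features (NA allowed).
#'
#' @param path file path
#' @return data.frame
#' @export
readFeatureMatrix <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  if (!all(c("gene", "chrom") %in% names(d)))
    stop("feature matrix needs leading columns 'gene' and 'chrom'")
  if (anyDuplicated(names(d))) stop("feature names must be unique")
  d
}

#' Write / read a gene likelihood matrix
#'
#' Genes x grid matrix of composite log-likelihoods; the header row
#' carries the grid s values.
#'
#' @param gl a [GeneLikelihoods-class]
#' @param path file path
#' @export
writeGeneLikelihoods <- function(gl, path) {
  L <- gl@loglik
  out <- data.frame(gene = rownames(L),
                    matrix(sprintf("%.17g", L), nrow(L), ncol(L)),
                    sprintf("%.17g", gl@neutralLoglik),
                    gl@nSites, gl@nVariantSites, check.names = FALSE)
  names(out) <- c("gene", sprintf("%.17g", gl@grid@s), "neutral",
                  "n_sites", "n_variant_sites")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneLikelihoods
#' @param pMiss the misannotation probability the file was computed at
#' @export
readGeneLikelihoods <- function(path, pMiss = NA_real_) {
  d <- read.delim(path, check.names = FALSE)
  meta <- c("gene", "neutral", "n_sites", "n_variant_sites")
  sCols <- setdiff(names(d), meta)
  grid <- selectionGrid(as.numeric(sCols))
  L <- as.matrix(d[, sCols, drop = FALSE])
  dimnames(L) <- list(d$gene, NULL)
  new("GeneLikelihoods", loglik = L,
      neutralLoglik = setNames(d$neutral, d$gene),
      nSites = setNames(as.integer(d$n_sites), d$gene),
      nVariantSites = setNames(as.integer(d$n_variant_sites), d$gene),
      pMiss = pMiss, grid = grid)
}
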