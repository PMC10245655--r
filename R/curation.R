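# LOF variant curation: consequence / confidence / pext / depth / region /
# flag filters, allele-number imputation, mutation-rate assignment, and
# enumeration of invariant sites.
#
# Annotated-variant tables are tab-delimited with columns (1-based,
# fully-closed VCF-style coordinates):
#   chrom, pos, ref, alt, gene, consequence, lof_confidence, flagged,
#   pext, depth, segdup, AC, AN, and either mu or (context, methylation).
# Site tables carry: gene, site_id, chrom_class (autosome|X), mu, AC, AN.

#' Filter configuration for LOF curation
#'
#' Defaults are the selected values of the curation grid: read-depth cutoff
#' 0x (effectively disabled, but exposed), mean-pext cutoff 0.05, drop
#' variants in segmental duplications or low-mappability regions, drop
#' variants flagged as potentially problematic, and keep only splice
#' acceptor, splice donor and stop gained consequences labelled High
#' Confidence by the upstream LOF annotation.
#'
#' @param depthCutoff minimum median read depth (>= 0)
#' @param pextCutoff minimum mean pext across tissues (>= 0)
#' @param dropSegdup drop segmental-duplication / low-mappability variants
#' @param dropFlagged drop variants flagged as potentially problematic
#' @param consequences allowed consequence classes
#' @param confidence required LOF-confidence label
#' @return a list of class \code{FilterConfig}
#' @export
filterConfig <- function(depthCutoff = 0, pextCutoff = 0.05,
                         dropSegdup = TRUE, dropFlagged = TRUE,
                         consequences = c("splice_acceptor", "splice_donor",
                                          "stop_gained"),
                         confidence = "HC") {
  stopifnot(depthCutoff >= 0, pextCutoff >= 0)
  structure(list(depthCutoff = depthCutoff, pextCutoff = pextCutoff,
                 dropSegdup = dropSegdup, dropFlagged = dropFlagged,
                 consequences = consequences, confidence = confidence),
            class = "FilterConfig")
}

#' Apply the LOF curation filters
#'
#' Filters are pure predicates, so the surviving set does not depend on
#' their order; the audit table counts drops in the documented application
#' order (consequence, confidence, pext, depth, region, flags). Rows with
#' missing pext or depth are not dropped by those filters (the cutoff
#' applies only where the value is known).
#'
#' @param variants annotated-variant data.frame (see file header columns)
#' @param config a [filterConfig()]
#' @return list(variants = surviving rows, audit = data.frame(filter,
#'   dropped, remaining))
#' @export
filterLofs <- function(variants, config = filterConfig()) {
  need <- c("gene", "consequence", "lof_confidence", "flagged", "pext",
            "depth", "segdup")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  preds <- list(
    consequence = variants$consequence %in% config$consequences,
    confidence = variants$lof_confidence %in% config$confidence,
    pext = is.na(variants$pext) | variants$pext >= config$pextCutoff,
    depth = is.na(variants$depth) | variants$depth >= config$depthCutoff,
    region = if (config$dropSegdup) !(variants$segdup %in% TRUE) else
      rep(TRUE, nrow(variants)),
    flags = if (config$dropFlagged) !(variants$flagged %in% TRUE) else
      rep(TRUE, nrow(variants)))
  keep <- rep(TRUE, nrow(variants))
  audit <- data.frame(filter = names(preds), dropped = NA_integer_,
                      remaining = NA_integer_)
  for (i in seq_along(preds)) {
    dropped <- keep & !preds[[i]]
    audit$dropped[i] <- sum(dropped)
    keep <- keep & preds[[i]]
    audit$remaining[i] <- sum(keep)
  }
  list(variants = variants[keep, , drop = FALSE], audit = audit)
}

#' Impute missing allele numbers
#'
#' Sites without a released AN (typically invariant sites) receive the
#' median AN of sites with observed AN, computed separately on the
#' autosomes and the X chromosome. The medians used are reported via a
#' message.
#'
#' @param sites site table with columns \code{chrom_class} (autosome|X) and
#'   \code{AN}
#' @return the site table with AN filled
#' @export
imputeAN <- function(sites) {
  stopifnot(all(c("chrom_class", "AN") %in% names(sites)))
  for (cls in unique(sites$chrom_class[is.na(sites$AN)])) {
    inCls <- sites$chrom_class == cls
    obs <- sites$AN[inCls & !is.na(sites$AN)]
    if (length(obs) == 0L)
      stop("no observed AN for chromosome class '", cls,
           "'; cannot impute")
    med <- as.integer(round(median(obs)))
    message("imputing AN = ", med, " for ", sum(inCls & is.na(sites$AN)),
            " site(s) on chromosome class '", cls, "'")
    sites$AN[inCls & is.na(sites$AN)] <- med
  }
  sites
}

#' Assign per-site mutation rates from a context table
#'
#' Rows with an explicit \code{mu} pass through unchanged; other rows are
#' resolved by their (context, methylation) key against \code{contextTable}
#' (columns context, methylation, mu). Unresolvable keys are fatal and name
#' the offending key.
#'
#' @param sites site or variant table
#' @param contextTable data.frame(context, methylation, mu)
#' @return the table with \code{mu} populated for every row
#' @export
assignMutationRates <- function(sites, contextTable = NULL) {
  if (!"mu" %in% names(sites)) sites$mu <- NA_real_
  todo <- is.na(sites$mu)
  if (!any(todo)) return(sites)
  if (is.null(contextTable))
    stop("rows without mu present but no context table supplied")
  key <- paste(sites$context[todo], sites$methylation[todo], sep = "|")
  tabKey <- paste(contextTable$context, contextTable$methylation, sep = "|")
  hit <- match(key, tabKey)
  if (anyNA(hit))
    stop("unresolvable mutational context key(s): ",
         paste(unique(key[is.na(hit)]), collapse = ", "))
  sites$mu[todo] <- contextTable$mu[hit]
  sites
}

#' Enumerate invariant sites
#'
#' Every possible LOF (after filtering) that is absent from the observed
#' variant set becomes an AC = 0 row; observed and invariant rows together
#' partition the filtered possible-LOF universe. Site identity is the
#' (chrom, pos, ref, alt) key. Observed variants missing from the universe
#' are a logged inconsistency (warning), not an error.
#'
#' @param allPossible filtered table of all possible LOF SNVs
#' @param observed filtered table of observed variants (AC > 0)
#' @return the invariant subset of \code{allPossible} with AC = 0 and AN NA
#' @export
enumerateInvariantSites <- function(allPossible, observed) {
  keyCols <- c("chrom", "pos", "ref", "alt")
  stopifnot(all(keyCols %in% names(allPossible)))
  pk <- do.call(paste, c(allPossible[keyCols], sep = ":"))
  ok <- do.call(paste, c(observed[keyCols], sep = ":"))
  stray <- setdiff(ok, pk)
  if (length(stray))
    warning(length(stray),
            " observed variant(s) absent from the possible-LOF universe")
  inv <- allPossible[!(pk %in% ok), , drop = FALSE]
  inv$AC <- 0L
  inv$AN <- NA_integer_
  inv
}

#' Curate a per-gene site table from annotated variant tables
#'
#' Runs the full curation chain: filter the possible-LOF universe and the
#' observed variants with the same config, enumerate invariant sites,
#' combine, impute AN, and assign mutation rates. The result is the site
#' table consumed by [geneCompositeLoglik()].
#'
#' @param allPossible all possible LOF SNVs (annotated-variant columns)
#' @param observed observed variants with AC/AN
#' @param config a [filterConfig()]
#' @param contextTable optional mutation-rate context table
#' @return list(sites, audit)
#' @export
curateSites <- function(allPossible, observed, config = filterConfig(),
                        contextTable = NULL) {
  fp <- filterLofs(allPossible, config)
  fo <- filterLofs(observed, config)
  inv <- enumerateInvariantSites(fp$variants, fo$variants)
  cols <- intersect(names(fo$variants), names(inv))
  sites <- rbind(fo$variants[, cols, drop = FALSE],
                 inv[, cols, drop = FALSE])
  if (!"chrom_class" %in% names(sites))
    sites$chrom_class <- ifelse(.normChrom(sites$chrom) == "X", "X",
                                "autosome")
  if (!"site_id" %in% names(sites))
    sites$site_id <- do.call(paste,
                             c(sites[c("chrom", "pos", "ref", "alt")],
                               sep = ":"))
  sites <- imputeAN(sites)
  sites <- assignMutationRates(sites, contextTable)
  list(sites = sites, audit = rbind(cbind(table = "possible", fp$audit),
                                    cbind(table = "observed", fo$audit)))
}
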