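#' Construct a demographic model
#'
#' @param durations integer vector of epoch durations in generations, oldest
#'   first; the first entry must be \code{NA} (burn-in epoch).
#' @param diploidSizes integer vector of diploid population sizes, one per
#'   epoch.
#' @return a [DemographicModel-class]
#' @examples
#' demographicModel(c(NA, 20), c(100, 1000))
#' @export
demographicModel <- function(durations, diploidSizes) {
  stopifnot(length(durations) == length(diploidSizes))
  e <- data.frame(duration = as.integer(durations),
                  diploidSize = as.integer(diploidSizes))
  hash <- paste(ifelse(is.na(e$duration), "b", e$duration),
                e$diploidSize, sep = "x", collapse = ";")
  new("DemographicModel", epochs = e, hash = hash)
}

#' Default desk-scale demography
#'
#' Burn-in at an ancestral diploid size of 100, followed by 20 generations
#' at diploid size 1000. This is the default used by the tests and the
#' synthetic-data generator; real analyses should supply their own
#' demography via [readDemography()].
#'
#' @return a [DemographicModel-class]
#' @export
defaultDemography <- function() demographicModel(c(NA, 20L), c(100L, 1000L))

#' Read a demography file
#'
#' Tab-delimited with columns \code{duration_generations} (positive integer,
#' or the literal \code{burnin} for the oldest row) and \code{diploid_size};
#' oldest epoch first.
#'
#' @param path file path
#' @return a [DemographicModel-class]
#' @export
readDemography <- function(path) {
  d <- read.delim(path, colClasses = c("character", "integer"))
  if (!all(c("duration_generations", "diploid_size") %in% names(d)))
    stop("demography file needs columns duration_generations, diploid_size")
  dur <- suppressWarnings(as.integer(d$duration_generations))
  dur[d$duration_generations == "burnin"] <- NA_integer_
  if (anyNA(dur) && which(is.na(dur)) != 1L)
    stop("only the oldest row may be 'burnin'")
  demographicModel(dur, d$diploid_size)
}

#' Write a demography file
#' @param demography a [DemographicModel-class]
#' @param path output path
#' @export
writeDemography <- function(demography, path) {
  e <- demography@epochs
  out <- data.frame(
    duration_generations = ifelse(is.na(e$duration), "burnin", e$duration),
    diploid_size = e$diploidSize)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Epoch table of a demographic model
#' @param demography a [DemographicModel-class]
#' @return data.frame of epochs (duration, diploidSize), oldest first
#' @export
epochTable <- function(demography) demography@epochs

#' Present-day diploid size
#' @param demography a [DemographicModel-class]
#' @export
presentSize <- function(demography) {
  e <- demography@epochs
  e$diploidSize[nrow(e)]
}

# epoch vectors as consumed by the C++ core (burn-in row carries duration 0)
.epochVectors <- function(demography) {
  e <- demography@epochs
  dur <- e$duration
  dur[1L] <- 0L
  list(durations = as.integer(dur), sizes = as.integer(e$diploidSize))
}
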