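# internal numerical helpers

# floor applied to likelihoods before taking logs; hits are counted by callers
.LOG_FLOOR <- log(1e-300)

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logSumExp for a matrix
rowLogSumExp <- function(X) {
  m <- apply(X, 1L, max)
  m + log(rowSums(exp(X - m)))
}

# log with a documented floor at 1e-300; returns the floored values and
# reports the number of floor hits via an attribute
flooredLog <- function(x) {
  hits <- sum(x < 1e-300)
  out <- log(pmax(x, 1e-300))
  attr(out, "floorHits") <- hits
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hex (de)serialization of raw vectors for text-only model persistence
.rawToHex <- function(r) {
  x <- as.character(r)
  n <- length(x)
  starts <- seq(1L, n, by = 4000L)
  vapply(starts, function(s)
    paste(x[s:min(s + 3999L, n)], collapse = ""), character(1L))
}

.hexToRaw <- function(lines) {
  s <- paste(lines, collapse = "")
  as.raw(strtoi(substring(s, seq(1L, nchar(s), 2L),
                          seq(2L, nchar(s), 2L)), 16L))
}
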