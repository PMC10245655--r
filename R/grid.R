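#' Construct a grid of s_het values
#'
#' @param s strictly increasing numeric vector in (0, 1].
#' @return a [SelectionGrid-class]
#' @export
selectionGrid <- function(s) new("SelectionGrid", s = as.numeric(s))

#' Default s_het grid
#'
#' 101 log-spaced points from 1e-8 to 1. The spacing places the selection
#' regime boundaries (1e-4, 1e-3, 1e-1) exactly on grid points. The neutral
#' point s = 0 backing the misannotation mixture is carried separately by
#' the likelihood machinery and is not part of the grid.
#'
#' @param n number of points
#' @param lower,upper grid bounds in (0, 1]
#' @return a [SelectionGrid-class]
#' @export
defaultSelectionGrid <- function(n = 101L, lower = 1e-8, upper = 1) {
  selectionGrid(10^seq(log10(lower), log10(upper), length.out = n))
}

#' Grid values
#' @param grid a [SelectionGrid-class]
#' @return numeric vector of s_het values
#' @export
gridValues <- function(grid) grid@s

# trapezoidal quadrature weights on the log10 scale; used when a continuous
# prior density is discretized onto the grid
.gridQuadWeights <- function(grid) {
  x <- log10(grid@s)
  n <- length(x)
  w <- numeric(n)
  w[1L] <- (x[2L] - x[1L]) / 2
  w[n] <- (x[n] - x[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  w
}

.gridHash <- function(grid) {
  s <- grid@s
  sprintf("g%d_%.6g_%.6g", length(s), s[1L], s[length(s)])
}
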