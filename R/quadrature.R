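#' Gauss-Hermite rule for Normal expectations
#'
#' Returns nodes and weights such that `sum(w * f(z))` approximates
#' `E[f(Z)]` for `Z ~ N(0, 1)`.  Rescale nodes by `sigma` for a
#' `N(0, sigma^2)` expectation.
#'
#' @param order number of quadrature nodes (>= 1).
#' @return list with numeric vectors `nodes` and `weights`; the weights
#'   sum to 1.
#' @examples
#' gh <- gauss_hermite_normal(21)
#' sum(gh$weights * gh$nodes^2)  # Var of a standard Normal, ~1
#' @export
gauss_hermite_normal <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || order < 1)
    stop("'order' must be a positive integer")
  order <- as.integer(order)
  if (order == 1L)
    return(list(nodes = 0, weights = 1))
  gh <- pracma::gaussHermite(order)
  list(nodes = sqrt(2) * gh$x, weights = gh$w / sqrt(pi))
}

## log(sum(exp(x))) along rows of a matrix, guarded against overflow
.logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}
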