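#' Gauss-Legendre quadrature rule on [-1, 1]
#'
#' Nodes and weights of the n-point Gauss-Legendre rule, exact for
#' polynomials up to degree 2n - 1. Computed by the Golub-Welsch
#' eigen-decomposition of the Jacobi matrix of the Legendre recurrence.
#'
#' @param n number of nodes (integer >= 1)
#' @return list with `nodes` (increasing) and `weights`, both length `n`
#' @examples
#' g <- gauss_legendre(3)
#' sum(g$weights * g$nodes^4)  # 2/5
#' @export
gauss_legendre <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("gauss_legendre: 'n' must be a positive integer")
  if (n == 1L) return(list(nodes = 0, weights = 2))
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)           # off-diagonal of the Jacobi matrix
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1L, idx]^2)
}
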