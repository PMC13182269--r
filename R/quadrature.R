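# Gaussian quadrature rules via the Golub-Welsch eigenvalue method.
# Nodes/weights are exact for polynomial integrands of degree <= 2n - 1.

#' Gauss-Hermite quadrature rule
#'
#' Nodes \eqn{x_k} and weights \eqn{w_k} such that
#' \eqn{\int f(x) e^{-x^2} dx \approx \sum_k w_k f(x_k)}.
#'
#' @param n number of nodes (>= 1).
#' @return list with numeric vectors `nodes` and `weights`.
#' @export
#' @examples
#' gh <- gauss_hermite(9)
#' sum(gh$weights)            # sqrt(pi)
#' sum(gh$weights * gh$nodes^2)  # sqrt(pi)/2
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = sqrt(pi) * e$vectors[1, idx]^2)
}

#' Gauss-Legendre quadrature rule on \[-1, 1\]
#'
#' @param n number of nodes (>= 1).
#' @return list with numeric vectors `nodes` and `weights`
#'   (`sum(weights) == 2`).
#' @export
gauss_legendre <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1)
  off <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = 2 * e$vectors[1, idx]^2)
}

# Tensor-product standard-normal rule in 2 dimensions: returns K = n^2 points
# z (K x 2) and normalised weights w (sum 1) such that
# E[f(Z)] for Z ~ N(0, I_2) ~= sum_k w_k f(z_k).
ghq_normal2d <- function(n) {
  gh <- gauss_hermite(n)
  z1 <- rep(gh$nodes, each = n)
  z2 <- rep(gh$nodes, times = n)
  w <- rep(gh$weights, each = n) * rep(gh$weights, times = n) / pi
  list(z = cbind(sqrt(2) * z1, sqrt(2) * z2), w = w)
}
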