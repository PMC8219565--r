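# Core one-parameter IRT primitives shared by the generator, the calibration
# routines and the DTF statistics. Items follow the partial credit model
#   P(X = k | theta) = exp(k*theta - sum_{l<=k} delta_l) / normalizer,
# with a dichotomous Rasch item as the single-step special case.

#' Partial-credit category probabilities for one item
#'
#' @param delta ordered step thresholds (logits); length K for an item with
#'   categories 0..K.
#' @param theta numeric vector of latent proficiencies.
#' @return matrix `length(theta) x (K + 1)` of category probabilities.
#' @export
pcm_probs <- function(delta, theta) {
  K <- length(delta)
  cum <- c(0, cumsum(delta))
  eta <- outer(theta, 0:K) - rep(cum, each = length(theta))
  eta <- eta - max(eta)  # scalar stabilization suffices: rows span few units
  ex <- exp(eta)
  ex / rowSums(ex)
}

#' Conditional item moments under the partial credit model
#'
#' Expected category score, conditional variance (the item information of a
#' unit-discrimination item) and third central moment, per proficiency value.
#'
#' @inheritParams pcm_probs
#' @return list with numeric vectors `e`, `v`, `m3`.
#' @export
pcm_moments <- function(delta, theta) {
  P <- pcm_probs(delta, theta)
  k <- 0:length(delta)
  e <- drop(P %*% k)
  v <- drop(P %*% (k^2)) - e^2
  m3 <- drop(P %*% (k^3)) - 3 * e * drop(P %*% (k^2)) + 2 * e^3
  list(e = e, v = v, m3 = m3)
}

#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights of the probabilists' normal-expectation rule, computed by
#' the Golub-Welsch eigendecomposition of the Jacobi matrix of the
#' (physicists') Hermite polynomials. The returned rule integrates
#' `E[g(Z)]` for `Z ~ N(0, 1)`: `sum(w * g(x))`.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`, both length `n`.
#' @export
gauss_hermite <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 1))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  # physicists' nodes x with weight w: E[g(Z)] = sum w_i g(sqrt(2) x_i)
  list(nodes = sqrt(2) * e$values[ord],
       weights = (e$vectors[1L, ord]^2))
}

# quadrature over N(mu, sigma2): nodes on the theta scale plus prior weights
normal_quadrature <- function(n_nodes, mu = 0, sigma2 = 1) {
  gh <- gauss_hermite(n_nodes)
  list(theta = mu + sqrt(sigma2) * gh$nodes, w = gh$weights)
}

# apply a uniform additive difficulty shift to every step of every item
shift_bank <- function(delta_list, shift) {
  if (shift == 0) return(delta_list)
  lapply(delta_list, function(d) d + shift)
}
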