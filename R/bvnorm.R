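# Bivariate-normal rectangle probabilities, vectorised over cells for a
# single correlation. Used by the polychoric likelihood, where every call
# evaluates all cells of one contingency table at one trial rho.
#
# P(a1 < X <= a2, b1 < Y <= b2) = int_{a1}^{a2} phi(x) *
#   [Phi((b2 - rho x)/s) - Phi((b1 - rho x)/s)] dx,  s = sqrt(1 - rho^2),
# evaluated with fixed-order Gauss-Legendre nodes per cell. Infinite
# thresholds are truncated at +-8.5 standard deviations (mass < 1e-17).

.gl64 <- local({
  # Golub-Welsch: nodes/weights for Legendre polynomials on [-1, 1]
  n <- 64L
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  ee <- eigen(J, symmetric = TRUE)
  list(nodes = rev(ee$values), weights = rev(2 * ee$vectors[1L, ]^2))
})

bvn_rect_prob <- function(a1, a2, b1, b2, rho) {
  stopifnot(length(rho) == 1L, abs(rho) < 1)
  lim <- 8.5
  a1 <- pmax(a1, -lim); a2 <- pmin(a2, lim)
  m <- length(a1)
  nd <- .gl64$nodes; wt <- .gl64$weights
  half <- (a2 - a1) / 2
  mid <- (a2 + a1) / 2
  # x: (nodes x cells) matrix of abscissae
  x <- outer(nd, half) + rep(mid, each = length(nd))
  s <- sqrt(1 - rho^2)
  u2 <- (rep(b2, each = length(nd)) - rho * x) / s
  u1 <- (rep(b1, each = length(nd)) - rho * x) / s
  f <- stats::dnorm(x) * (stats::pnorm(u2) - stats::pnorm(u1))
  pr <- half * colSums(wt * matrix(f, nrow = length(nd)))
  pmax(pr, 0)
}
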