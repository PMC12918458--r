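# Small generating models and simulation helpers shared across tests.

tiny_spec <- function(phi_val = 0.4, loading = 0.7, criteria = NULL,
                      categories = c(4L, 5L)) {
  traits <- c("t1", "t2")
  methods <- list(A = list(n_items = 3L, categories = categories[1L]),
                  B = list(n_items = 3L, categories = categories[2L]))
  q <- 4L
  phi <- matrix(phi_val, q, q); diag(phi) <- 1
  mtmm_model_spec(traits, methods, loadings = rep(loading, 12L), phi = phi,
                  criteria = criteria)
}

# latent bivariate-normal ordinal pair, for polychoric recovery checks
simulate_ordinal_pair <- function(n, rho, tau_x, tau_y, seed = 1) {
  set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  list(x = findInterval(z1, tau_x) + 1L, y = findInterval(z2, tau_y) + 1L)
}

# independent oracle for bivariate-normal rectangle probabilities:
# adaptive 1-D quadrature of the closed-form conditional representation
bvn_rect_oracle <- function(a1, a2, b1, b2, rho) {
  s <- sqrt(1 - rho^2)
  f <- function(x) {
    stats::dnorm(x) * (stats::pnorm((b2 - rho * x) / s) -
                         stats::pnorm((b1 - rho * x) / s))
  }
  stats::integrate(f, max(a1, -10), min(a2, 10), rel.tol = 1e-10)$value
}

# independent oracle for the JZS Bayes factor: 1e6-point trapezoid rule on
# the t = g/(1+g) scale, entirely separate from the adaptive-quadrature path
jzs_bf10_trapezoid <- function(r2, n, p, r_scale = sqrt(2) / 4,
                               grid = 1e6) {
  b <- n * r_scale^2 / 2
  t <- seq(1e-9, 1 - 1e-9, length.out = grid)
  g <- t / (1 - t)
  logf <- 0.5 * (n - p - 1) * log1p(g) -
    0.5 * (n - 1) * log1p(g * (1 - r2)) +
    0.5 * log(b) - lgamma(0.5) - 1.5 * log(g) - b / g +
    2 * log(1 / (1 - t))
  m <- max(logf)
  h <- t[2L] - t[1L]
  v <- exp(logf - m)
  exp(m) * h * (sum(v) - (v[1L] + v[grid]) / 2)
}
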