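test_that("pearson_matrix reproduces hand-computed correlations", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4), z = c(4, 3, 2, 1))
  pm <- pearson_matrix(d)
  expect_equal(pm$values["x", "x"], 1)
  expect_equal(pm$values["x", "y"], 0.8)
  expect_equal(pm$values["x", "z"], -1)
  expect_true(is_corr_matrix(replace(pm$values, is.na(pm$values), 0)))
})

test_that("pearson_matrix flags zero-variance columns", {
  d <- data.frame(x = c(1, 2, 3, 4), c = rep(1, 4))
  pm <- pearson_matrix(d)
  expect_identical(attr(pm, "undefined"), "c")
  expect_true(is.na(pm$values["x", "c"]))
  expect_equal(pm$values["c", "c"], 1)
})

test_that("fisher z transform, inverse and rejection", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  for (r in c(-0.95, -0.3, 0, 0.42, 0.87, 0.999)) {
    expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
  }
  expect_error(fisher_z(1), "< 1")
  expect_error(fisher_z(-1.2), "< 1")
})

test_that("bivariate-normal rectangle probabilities match adaptive quadrature", {
  cells <- list(c(-Inf, 0.3, -Inf, -0.2), c(-0.5, 0.5, -1, 1),
                c(0.8, Inf, -Inf, 0), c(-2, -0.5, 0.5, 2))
  for (rho in c(-0.9, -0.4, 0, 0.5, 0.927, 0.99)) {
    for (cl in cells) {
      got <- nomoscan:::bvn_rect_prob(cl[1], cl[2], cl[3], cl[4], rho)
      want <- bvn_rect_oracle(cl[1], cl[2], cl[3], cl[4], rho)
      expect_equal(got, want, tolerance = 1e-7)
    }
  }
  # independence factorises
  expect_equal(nomoscan:::bvn_rect_prob(-Inf, 0, -Inf, 1, 0),
               pnorm(0) * pnorm(1), tolerance = 1e-10)
})

test_that("polychoric correlation: independence, boundary, recovery", {
  # independence: table equal to the outer product of margins
  x <- rep(1:3, times = c(20, 50, 30))
  y <- rep(rep(1:2, times = c(40, 60)), length.out = 100)
  xy <- expand.grid(x = 1:3, y = 1:2)
  n_cell <- outer(c(20, 50, 30), c(40, 60)) / 100
  xx <- rep(xy$x, as.vector(n_cell)); yy <- rep(xy$y, as.vector(n_cell))
  est <- polychoric_corr(xx, yy)
  expect_lt(abs(est$rho), 0.01)

  # perfectly monotone 2x2 table pushes to the +0.999 clip
  mono <- polychoric_corr(rep(1:2, each = 50), rep(1:2, each = 50))
  expect_equal(mono$rho, 0.999)

  # Monte-Carlo recovery at rho = .5, 3 categories
  d <- simulate_ordinal_pair(50000, 0.5, c(-0.6, 0.6), c(-0.4, 0.8),
                             seed = 11)
  est <- polychoric_corr(d$x, d$y)
  expect_equal(est$rho, 0.5, tolerance = 0.02)
  expect_true(est$var > 0 && est$var < 1e-3)

  expect_error(polychoric_corr(rep(1L, 50), rep(1:2, 25),
                               names = c("v7", "v8")), "v7")
})

test_that("polychoric_matrix output is a smoothed correlation matrix", {
  spec <- tiny_spec()
  sim <- simulate_mtmm(spec, 400, seed = 3)
  pm <- polychoric_matrix(sim$items)
  expect_true(is_corr_matrix(pm$values))
  ev <- eigen(pm$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  V <- attr(pm, "asymp_var")
  expect_true(all(V[lower.tri(V)] > 0))
})

test_that("standardized_ols matches hand computation and raw-data lm", {
  labs <- c("y", "x1", "x2", "x3")
  # orthogonal predictors: beta equals zero-order correlations
  R <- diag(4); dimnames(R) <- list(labs, labs)
  R["y", c("x1", "x2", "x3")] <- R[c("x1", "x2", "x3"), "y"] <- c(.3, .2, .1)
  fit <- standardized_ols(R, "y", c("x1", "x2", "x3"), n = 100)
  expect_equal(unname(fit$beta), c(.3, .2, .1))
  expect_equal(fit$r_squared, 0.14)

  # 2x2 inversion by hand: r12 = .5, r1y = .5, r2y = .4
  R2 <- diag(3); dimnames(R2) <- list(labs[1:3], labs[1:3])
  R2["x1", "x2"] <- R2["x2", "x1"] <- .5
  R2["y", "x1"] <- R2["x1", "y"] <- .5
  R2["y", "x2"] <- R2["x2", "y"] <- .4
  fit2 <- standardized_ols(R2, "y", c("x1", "x2"), n = 50)
  expect_equal(unname(fit2$beta), c(0.4, 0.2))
  expect_equal(fit2$r_squared, 0.28)

  # agreement with a generic least-squares fit on standardized raw data
  set.seed(42)
  X <- matrix(rnorm(600), 200)
  y <- 0.4 * X[, 1] - 0.3 * X[, 2] + rnorm(200)
  d <- data.frame(y = y, x1 = X[, 1], x2 = X[, 2], x3 = X[, 3])
  zd <- as.data.frame(scale(d))
  ref <- lm(y ~ x1 + x2 + x3 - 1, data = zd)
  fit3 <- standardized_ols(pearson_matrix(d), "y", c("x1", "x2", "x3"),
                           n = 200)
  expect_equal(unname(fit3$beta), unname(coef(ref)), tolerance = 1e-8)
  sm <- summary(ref)
  expect_equal(fit3$r_squared, sm$r.squared, tolerance = 1e-8)

  # collinear predictors rejected with names
  d$x4 <- d$x1
  expect_error(standardized_ols(pearson_matrix(d), "y", c("x1", "x4"), 200),
               "singular")
})
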