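test_that("model spec validation catches bad inputs", {
  # identity phi: implied cross-factor item correlations are all zero
  spec0 <- tiny_spec(phi_val = 0)
  imp <- implied_item_corr(spec0)
  cross <- outer(spec0$assignment, spec0$assignment, `!=`)
  expect_true(all(imp[cross] == 0))

  # default two-inventory preset: 39 items, 6 factors
  spec <- default_mtmm_spec("sd3dd", include_criteria = FALSE)
  expect_length(spec$items, 39L)
  expect_length(spec$factors, 6L)
  expect_equal(unname(spec$phi["mach.SD3", "mach.DD"]), 0.927)

  # invalid factor correlation rejected
  bad_phi <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(
    mtmm_model_spec(c("t1"), list(A = list(n_items = 2L, categories = 3L),
                                  B = list(n_items = 2L, categories = 3L)),
                    loadings = rep(.5, 4), phi = bad_phi),
    "correlation matrix")
  # non-PD phi rejected naming the eigenvalue
  npd <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3)
  expect_error(
    mtmm_model_spec(c("t1", "t2", "t3"),
                    list(A = list(n_items = 1L, categories = 3L)),
                    loadings = rep(.5, 3), phi = npd, shared_traits = TRUE),
    "eigenvalue")
  # non-increasing thresholds rejected
  expect_error(
    mtmm_model_spec(c("t1"), list(A = list(n_items = 1L, categories = 3L)),
                    loadings = .5, thresholds = list(c(0.5, 0.5)),
                    shared_traits = TRUE),
    "strictly increasing")
})

test_that("latent scores are deterministic and recover phi", {
  spec <- default_mtmm_spec("sd3dd", include_criteria = FALSE)
  a <- simulate_latent_scores(spec, 200, seed = 9)
  b <- simulate_latent_scores(spec, 200, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_latent_scores(spec, 1, seed = 1), ">= 2")

  big <- simulate_latent_scores(spec, 100000, seed = 5)
  emp <- cor(big)
  expect_lt(abs(emp["mach.SD3", "mach.DD"] - 0.927), 0.01)

  spec0 <- tiny_spec(phi_val = 0)
  big0 <- cor(simulate_latent_scores(spec0, 100000, seed = 5))
  expect_lt(max(abs(big0[lower.tri(big0)])), 0.02)
})

test_that("discretization honours thresholds and marginals", {
  expect_equal(drop(discretize_to_likert(cbind(c(-1, 2)), list(0))),
               c(1L, 2L))
  expect_equal(drop(discretize_to_likert(cbind(c(-5, -4)), list(c(0, 1)))),
               c(1L, 1L))
  set.seed(2)
  z <- cbind(rnorm(100000))
  resp <- discretize_to_likert(z, list(c(-0.5, 0.5)))
  expect_lt(abs(mean(resp == 2L) - (pnorm(0.5) - pnorm(-0.5))), 0.005)
  # boundary rule: category c iff value in (tau_{c-1}, tau_c]
  expect_equal(drop(discretize_to_likert(cbind(0), list(0))), 1L)
})

test_that("criterion generation is seeded and hits its population R2", {
  traits <- c("t1", "t2", "t3")
  crit <- data.frame(criterion = "y", set = "s",
                     w.t1 = .4, w.t2 = .2, w.t3 = .1,
                     residual_sd = NA_real_)
  spec <- mtmm_model_spec(
    traits, list(A = list(n_items = 2L, categories = 3L)),
    loadings = rep(.6, 6), phi = diag(3), criteria = crit,
    shared_traits = TRUE)
  F <- simulate_latent_scores(spec, 100000, seed = 4)
  y1 <- simulate_criterion_scores(F, spec, seed = 8)
  y2 <- simulate_criterion_scores(F, spec, seed = 8)
  expect_identical(y1, y2)
  r2 <- summary(lm(y1$y ~ F))$r.squared
  expect_equal(r2, 0.21, tolerance = 0.01)

  # zero weights: criterion uncorrelated with traits
  spec0 <- spec
  spec0$criteria[, c("w.t1", "w.t2", "w.t3")] <- 0
  y0 <- simulate_criterion_scores(F, spec0, seed = 8)
  expect_lt(max(abs(cor(y0$y, F))), 0.02)

  # negative residual sd rejected
  crit_bad <- crit; crit_bad$residual_sd <- -1
  expect_error(
    mtmm_model_spec(traits, list(A = list(n_items = 2L, categories = 3L)),
                    loadings = rep(.6, 6), phi = diag(3),
                    criteria = crit_bad, shared_traits = TRUE),
    "nonnegative")
})

test_that("full simulation is deterministic and matches implied moments", {
  spec <- tiny_spec(phi_val = 0.45, loading = 0.75)
  s1 <- simulate_mtmm(spec, 300, seed = 21)
  s2 <- simulate_mtmm(spec, 300, seed = 21)
  expect_identical(s1$items, s2$items)
  expect_identical(s1$criteria, s2$criteria)

  # moment recovery on a reduced 12-item design (scaled-down from the
  # full-design check that lives in the acceptance suite)
  big <- simulate_mtmm(spec, 100000, seed = 13)
  pm <- polychoric_matrix(big$items)
  imp <- implied_item_corr(spec)
  expect_lt(max(abs(pm$values - imp)), 0.02)
})
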