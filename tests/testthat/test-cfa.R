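test_that("model-implied correlations follow common-factor algebra", {
  idx <- c(1L, 1L, 2L)
  phi <- matrix(c(1, .5, .5, 1), 2)
  expect_equal(model_implied_corr(rep(0, 3), phi, idx), diag(3))
  R <- model_implied_corr(c(.8, .8, .5), phi, idx)
  expect_equal(R[1, 2], 0.64)  # same factor
  expect_equal(R[1, 3], 0.20)  # .8 * .5 * phi12
  expect_true(is_corr_matrix(R))
})

test_that("df arithmetic and constraints", {
  spec <- default_mtmm_spec("sd3dd", include_criteria = FALSE)
  cspec <- cfa_model_spec(setNames(spec$assignment, spec$items))
  expect_equal(cspec$n_free, 39L + 15L)
  expect_equal(cfa_df(cspec), 687L)
  fx <- data.frame(f1 = "mach.SD3", f2 = "mach.DD", value = 1)
  cspec_c <- cfa_model_spec(setNames(spec$assignment, spec$items),
                            fixed_corr = fx)
  expect_equal(cfa_df(cspec_c), 688L)
  expect_error(cfa_model_spec(c(i1 = "f1"), fixed_corr = data.frame(
    f1 = "f1", f2 = "nope", value = 1)), "unknown factors")
})

test_that("DWLS has a zero-residual fixed point (ULS and DWLS weights)", {
  set.seed(5)
  lam <- runif(12, 0.4, 0.85)
  phi <- matrix(0.35, 4, 4); diag(phi) <- 1
  assign <- setNames(rep(paste0("f", 1:4), each = 3), paste0("i", 1:12))
  S <- model_implied_corr(lam, phi, match(assign, unique(assign)),
                          labels = names(assign))
  cspec <- cfa_model_spec(assign)
  cm <- corr_matrix(S, n = 1000)
  attr(cm, "asymp_var") <- matrix(2e-3, 12, 12,
                                  dimnames = dimnames(S))
  for (w in c("uls", "dwls")) {
    fit <- fit_dwls(cm, cspec, N = 1000, weights = w)
    expect_true(fit$converged)
    expect_lt(fit$F_min, 1e-8)
    expect_lt(max(abs(fit$loadings - lam)), 1e-4)
    expect_lt(max(abs(fit$phi - phi)), 1e-4)
  }
})

test_that("analytic gradient matches a finite-difference check", {
  set.seed(8)
  assign <- setNames(rep(c("f1", "f2"), each = 3), paste0("i", 1:6))
  cspec <- cfa_model_spec(assign)
  S <- model_implied_corr(runif(6, .3, .8),
                          matrix(c(1, .4, .4, 1), 2),
                          match(assign, unique(assign)),
                          labels = names(assign))
  Winv <- matrix(1, 6, 6); diag(Winv) <- 0
  par <- c(runif(6, .2, .7), 0.25)
  g <- nomoscan:::dwls_gradient(par, S, Winv, cspec)
  fd <- vapply(seq_along(par), function(j) {
    h <- 1e-6; e <- numeric(length(par)); e[j] <- h
    (nomoscan:::dwls_objective(par + e, S, Winv, cspec) -
       nomoscan:::dwls_objective(par - e, S, Winv, cspec)) / (2 * h)
  }, numeric(1))
  expect_equal(unname(g), fd, tolerance = 1e-5)
})

test_that("fit indices equal their closed forms on constructed fits", {
  mk <- function(T, df, N) {
    res <- matrix(0, 3, 3)
    list(chi_square = T, df = df, N = N, sample_corr = res, implied = res)
  }
  expect_equal(fit_indices(mk(100, 100, 200), mk(900, 105, 200))[
    c("cfi", "rmsea")], list(cfi = 1, rmsea = 0))
  expect_equal(fit_indices(mk(150, 100, 200), mk(605, 105, 200))$cfi, 0.9)
  expect_equal(fit_indices(mk(200, 100, 101), mk(900, 105, 101))$rmsea, 0.1)
  # df = 0 flags RMSEA undefined
  expect_true(is.na(fit_indices(mk(0, 0, 101), mk(900, 105, 101))$rmsea))
  # SRMR: root mean square of residual correlations
  f <- mk(100, 100, 200); b <- mk(900, 105, 200)
  f$sample_corr <- matrix(c(1, .3, .2, .3, 1, .1, .2, .1, 1), 3)
  f$implied <- diag(3)
  expect_equal(fit_indices(f, b)$srmr, sqrt(mean(c(.3, .2, .1)^2)))
})

test_that("AVE, Fornell-Larcker and HTMT behave as defined", {
  expect_equal(compute_ave(c(.8, .8, .8)), .64)
  expect_equal(compute_ave(c(.6, .8)), .50)
  expect_equal(compute_ave(c(0, 0)), 0)

  phi <- matrix(c(1, .927, .927, 1), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  fl <- fornell_larcker(c(a = .302, b = .676), phi)
  expect_false(fl$pass[["a"]])   # sqrt(.302) = .5495 < .927
  phi2 <- matrix(c(1, .5, .5, 1), 2, dimnames = dimnames(phi))
  expect_true(all(fornell_larcker(c(a = .81, b = .81), phi2)$pass))
  # exact tie fails (strict inequality)
  phi3 <- matrix(c(1, .9, .9, 1), 2, dimnames = dimnames(phi))
  expect_false(fornell_larcker(c(a = .81, b = .95), phi3)$pass[["a"]])

  mk_corr <- function(between, wa, wb) {
    R <- diag(4)
    R[1, 2] <- R[2, 1] <- wa
    R[3, 4] <- R[4, 3] <- wb
    R[1:2, 3:4] <- between; R[3:4, 1:2] <- between
    dimnames(R) <- list(paste0("i", 1:4), paste0("i", 1:4))
    R
  }
  h <- htmt(mk_corr(.3, .6, .6), c("i1", "i2"), c("i3", "i4"))
  expect_equal(h$htmt, 0.5)
  expect_equal(htmt(mk_corr(.3, .6, .6), c("i1", "i2"), c("i3", "i4"),
                    denominator = "geometric")$htmt, 0.5)
  # all correlations equal: the one-construct limiting case, HTMT = 1
  expect_equal(htmt(mk_corr(.6, .6, .6), c("i1", "i2"), c("i3", "i4"))$htmt,
               1.0)
  expect_equal(htmt(mk_corr(.3, .4, .9), c("i1", "i2"), c("i3", "i4"))$htmt,
               0.3 / 0.65)
  expect_equal(htmt(mk_corr(.3, .4, .9), c("i1", "i2"), c("i3", "i4"),
                    denominator = "geometric")$htmt, 0.5)
  # permutation invariance within sets
  expect_equal(htmt(mk_corr(.3, .4, .9), c("i2", "i1"), c("i4", "i3"))$htmt,
               0.3 / 0.65)
  # non-positive denominator flagged
  expect_true(htmt(mk_corr(.3, -.5, .1), c("i1", "i2"),
                   c("i3", "i4"))$undefined)
})

test_that("nested comparison reproduces printed delta chi-squares", {
  mk <- function(T, df) list(chi_square = T, df = df, N = 504)
  same <- compare_nested(mk(100, 687), mk(100, 688))
  expect_equal(same$delta_chi_square, 0)
  expect_equal(same$p_value, 1)

  cmp <- compare_nested(mk(1801.18, 687), mk(1801.18 + 13.42, 688))
  expect_equal(cmp$delta_chi_square, 13.42, tolerance = 1e-10)
  expect_equal(cmp$delta_df, 1L)
  expect_lt(cmp$p_value, 0.001)
  expect_lt(compare_nested(mk(1801.18, 687),
                           mk(1801.18 + 73.23, 688))$p_value, 0.001)
  # estimation anomaly flagged
  an <- compare_nested(mk(100, 687), mk(99, 688))
  expect_true(an$anomaly)
  expect_error(compare_nested(mk(100, 688), mk(100, 687)), "more df")
})
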