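prof <- function(r, trait = "t", method = "m", n = 504) {
  corr_profile(trait, method, paste0("c", seq_along(r)), r, n)
}

test_that("delta_r_bar: closed form, symmetry, rules", {
  a <- prof(c(.3, .2)); b <- prof(c(.1, .4))
  expect_equal(delta_r_bar(a, a)$delta_r_bar, 0)
  d <- delta_r_bar(a, b)
  expect_equal(d$delta_r_bar,
               tanh(mean(abs(atanh(c(.3, .2)) - atanh(c(.1, .4))))))
  expect_equal(d$delta_r_bar, 0.2118, tolerance = 1e-4)
  expect_equal(delta_r_bar(b, a)$delta_r_bar, d$delta_r_bar)
  expect_equal(delta_r_bar(a, b, rule = "raw")$delta_r_bar, 0.2)
  mismatched <- corr_profile("t", "m", c("x1", "x2"), c(.3, .2), 504)
  expect_error(delta_r_bar(a, mismatched), "identical criteria")
})

test_that("delta_R2_bar is the difference of means", {
  t1 <- read_reference_regressions()
  pe <- t1[t1$set == "psychopathy_empathy", ]
  expect_equal(delta_R2_bar(pe$r2[pe$method == "SD3"],
                            pe$r2[pe$method == "DD"]), 0.015)
  mh <- t1[t1$set == "mental_health", ]
  expect_equal(round(delta_R2_bar(mh$r2[mh$method == "SD3"],
                                  mh$r2[mh$method == "DD"]), 3), 0.087)
  expect_equal(delta_R2_bar(c(.1, .2), c(.1, .2)), 0)
  # difference of means, not mean of differences
  expect_equal(delta_R2_bar(c(.1, .3), c(.3, .1)), 0)
  expect_error(delta_R2_bar(numeric(0), numeric(0)), "non-empty")
})

test_that("profile ICC: identity, reversal, degenerate input", {
  a <- prof(c(.1, .3, .5))
  expect_equal(profile_icc(a, a)$icc, 1.0)
  # reversed two-point profile, raw double entry
  r1 <- prof(c(.1, .5)); r2 <- prof(c(.5, .1))
  expect_equal(profile_icc(r1, r2, fisher = FALSE)$icc, -1.0)
  const <- prof(c(.2, .2, .2))
  expect_true(profile_icc(const, const)$undefined)
  # the two-way absolute-agreement variant is 1 on identical profiles too
  expect_equal(profile_icc(a, a, rule = "icc_a1")$icc, 1.0)
})

test_that("pairwise Fisher z test matches its closed form", {
  eq <- compare_correlation_pair(.4, 504, .4, 504)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  t2 <- compare_correlation_pair(.3, 504, .1, 504)
  expect_equal(t2$z, 3.311, tolerance = 1e-3)
  expect_equal(t2$p_value, 0.00093, tolerance = 1e-2)
  # p strictly decreases with n at a fixed correlation difference
  ps <- vapply(c(50, 100, 400, 1600), function(n)
    compare_correlation_pair(.3, n, .1, n)$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(compare_correlation_pair(.3, 3, .1, 504), "n > 3")
  expect_error(compare_correlation_pair(1, 504, .1, 504), "< 1")
})

test_that("agreement percentage and its invariances", {
  t3 <- read_reference_bf01()
  pe <- t3[t3$set == "psychopathy_empathy", ]
  ca <- unlist(lapply(c("mach", "nar", "psych"), function(tr)
    classify_evidence(pe[[paste0("SD3_", tr)]])))
  cb <- unlist(lapply(c("mach", "nar", "psych"), function(tr)
    classify_evidence(pe[[paste0("DD_", tr)]])))
  expect_equal(round(agreement_percentage(ca, cb), 1), 38.1)
  expect_equal(agreement_percentage(ca, ca), 100)
  expect_equal(agreement_percentage(c("a", "b"), c("b", "a")), 0)
  # invariant to reordering cells and consistent relabeling
  perm <- sample(length(ca))
  expect_equal(agreement_percentage(ca[perm], cb[perm]),
               agreement_percentage(ca, cb))
  map <- c(`favors-omission` = "O", `favors-inclusion` = "I",
           inconclusive = "U")
  expect_equal(agreement_percentage(map[ca], map[cb]),
               agreement_percentage(ca, cb))
  expect_error(agreement_percentage(ca, ca[-1]), "equal length")
})

test_that("benchmarks apply the stated cutoffs with closed inequalities", {
  ideal <- evaluate_benchmarks("s", delta_r = 0, delta_R2 = 0,
                               icc = c(1, 1, 1), z_p = rep(1, 5),
                               agreement = 100)
  expect_true(all(ideal$flags))
  expect_true(ideal$overall)
  # boundary values pass (closed inequalities)
  boundary <- evaluate_benchmarks("s", delta_r = 0.10, delta_R2 = 0.05,
                                  icc = c(.80, .9), z_p = c(.05, .2),
                                  agreement = 80)
  expect_true(all(boundary$flags))
  # a large profile difference fails its criterion
  fail <- evaluate_benchmarks("s", delta_r = 0.315, delta_R2 = 0.01,
                              icc = c(.9), z_p = c(.5), agreement = 90)
  expect_false(fail$flags[["delta_r"]])
  expect_false(fail$overall)
  # missing component: not-evaluable, never a silent pass
  partial <- evaluate_benchmarks("s", delta_R2 = 0.01, agreement = 90)
  expect_true(is.na(partial$flags[["delta_r"]]))
  expect_true(is.na(partial$overall))
})

test_that("fixture mode reproduces every printed summary value", {
  res <- consistency_from_tables(read_reference_regressions(),
                                 read_reference_bf01())
  expect_equal(round(unname(res$delta_R2), 3),
               c(0.015, 0.049, 0.087, 0.020))
  expect_equal(round(unname(res$agreement), 2),
               c(38.10, 46.67, 38.89, 46.67))
  # every agreement falls below the 80% cutoff
  for (b in res$benchmarks) expect_false(b$flags[["agreement"]])
})

test_that("dependent-correlations test sharpens with dependence", {
  # zero difference: z = 0 regardless of the dependence
  eq <- compare_correlation_pair_dependent(.4, .4, .6, 504)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  # direct evaluation of the Case-A closed form
  r_jk <- .3; r_jh <- .1; r_kh <- .5; n <- 504
  cjj <- (r_kh * (1 - r_jk^2 - r_jh^2) -
            0.5 * r_jk * r_jh * (1 - r_jk^2 - r_jh^2 - r_kh^2)) /
    ((1 - r_jk^2) * (1 - r_jh^2))
  z_exp <- sqrt(n - 3) * (atanh(.3) - atanh(.1)) / sqrt(2 - 2 * cjj)
  got <- compare_correlation_pair_dependent(r_jk, r_jh, r_kh, n)
  expect_equal(got$z, z_exp)
  # stronger dependence -> larger |z| for the same difference, and the
  # independent-samples test is recovered at c = 0
  z_weak <- compare_correlation_pair_dependent(.3, .1, .2, n)$z
  expect_gt(got$z, z_weak)
  expect_gt(z_weak, compare_correlation_pair(.3, n, .1, n)$z * 0.9)
  expect_error(compare_correlation_pair_dependent(.3, .1, 1, 504), "< 1")
})
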