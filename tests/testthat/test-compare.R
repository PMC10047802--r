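# Post-hoc parsimony testing: drop-one refits, bivariate K-S, adjustment.

test_that("two-sample bivariate K-S has the expected degenerate behavior", {
  withr::with_seed(1, A <- matrix(rnorm(60), ncol = 2))
  same <- ks_two_sample(A, A, n_perm = 99, seed = 1)
  expect_identical(same$statistic, 0)
  expect_equal(same$p.value, 1, tolerance = 1e-12)
  # symmetry under swapping samples
  withr::with_seed(2, B <- matrix(rnorm(80, 0.5), ncol = 2))
  d1 <- ks_two_sample(A, B, n_perm = 49, seed = 3)$statistic
  d2 <- ks_two_sample(B, A, n_perm = 49, seed = 3)$statistic
  expect_equal(d1, d2, tolerance = 1e-12)
  # small samples warn
  expect_warning(ks_two_sample(A[1:5, ], B, n_perm = 9, seed = 1),
                 "sample size")
})

test_that("the K-S test separates shifted distributions", {
  withr::with_seed(10, {
    A <- matrix(rnorm(400), ncol = 2)
    B <- matrix(rnorm(400, mean = 3), ncol = 2)
  })
  res <- ks_two_sample(A, B, n_perm = 199, seed = 4)
  expect_lt(res$p.value, 0.01)
  expect_gt(res$statistic, 0.5)
})

test_that("multiplicity adjustments behave canonically", {
  # singleton: any method returns the raw p-value
  one <- adjust_pvalues(0.01)
  expect_equal(one$p_bonferroni, 0.01)
  expect_equal(one$p_bh, 0.01)
  # 50 tests at p = 0.01: Bonferroni adjusts to 0.5, not rejected
  many <- adjust_pvalues(c(0.01, runif(49, 0.5, 1)))
  expect_equal(many$p_bonferroni[1], 0.5)
  expect_false(many$reject_bonferroni[1])
  # rejection-set nesting Bonferroni <= Holm <= B-H on arbitrary p
  withr::with_seed(6, p <- runif(40)^2)
  adj <- adjust_pvalues(p)
  expect_true(all(!adj$reject_bonferroni | adj$reject_holm))
  expect_true(all(!adj$reject_holm | adj$reject_bh))
})

test_that("familywise error stays controlled under the uniform null", {
  withr::with_seed(11, {
    fw_bonf <- 0; fw_holm <- 0
    reps <- 300
    for (r in 1:reps) {
      p <- runif(20)
      adj <- adjust_pvalues(p)
      fw_bonf <- fw_bonf + any(adj$reject_bonferroni)
      fw_holm <- fw_holm + any(adj$reject_holm)
    }
  })
  expect_lt(fw_bonf / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  expect_lt(fw_holm / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("drop_smallest_term removes the weakest interaction only", {
  ds <- tiny_dataset_1d(n = 20, K = 3, M = 1)
  F1 <- structure(list(terms = list(
    fracpde:::fp_term(0.1, c(uxx = 1L)),     # diffusion: protected
    fracpde:::fp_term(5, c(u = 1L)),
    fracpde:::fp_term(0.001, c(v = 1L))),
    alpha = NA_real_), class = "fp_expression")
  F2 <- structure(list(terms = list(
    fracpde:::fp_term(10, c(vxx = 1L)),
    fracpde:::fp_term(1, c(u = 1L))),
    alpha = NA_real_), class = "fp_expression")
  red <- drop_smallest_term(F1, F2, ds)
  expect_identical(red$removed, "v")
  expect_identical(red$from, 1L)
  expect_length(red$F1$terms, 2)
  # diffusion never removed even when its norm is smallest
  F1b <- structure(list(terms = list(
    fracpde:::fp_term(1e-8, c(uxx = 1L)),
    fracpde:::fp_term(5, c(u = 1L)),
    fracpde:::fp_term(2, c(v = 1L))),
    alpha = NA_real_), class = "fp_expression")
  redb <- drop_smallest_term(F1b, F2, ds)
  labs <- vapply(redb$F1$terms, fracpde:::term_label, "")
  expect_true("uxx" %in% labs)
})

test_that("posthoc comparison rejects nothing under the complete null and
          everything against a zero model", {
  # true Example-1 dynamics on a small grid as the reference trajectory
  truthm <- list(
    F1 = structure(list(terms = list(
      fracpde:::fp_term(0.3, c(uxx = 1L)), fracpde:::fp_term(0.3, c(uyy = 1L)),
      fracpde:::fp_term(1), fracpde:::fp_term(-1, c(u = 1L))),
      alpha = NA_real_), class = "fp_expression"),
    F2 = structure(list(terms = list(
      fracpde:::fp_term(0.4, c(vxx = 1L)), fracpde:::fp_term(0.4, c(vyy = 1L)),
      fracpde:::fp_term(0.4), fracpde:::fp_term(-0.2, c(v = 1L))),
      alpha = NA_real_), class = "fp_expression"))
  g <- fp_grid(c(-5, 5), 16, dim = 2)
  ic <- random_initial_condition(g, seed = 21)
  times <- seq(0, 0.1, by = 0.02)
  truth <- predict_sparse(truthm, ic$u0, ic$v0, g, times)
  # complete null: model2 identical to model1
  rep0 <- posthoc_compare(truthm, truthm, truth, g, n_sub = 60,
                          n_perm = 99, seed = 5)
  expect_true(all(rep0$rejections <= 0.05 * length(times[-1])))
  # grossly wrong model2: zero right-hand side
  zero <- list(
    F1 = structure(list(terms = list(), alpha = NA_real_),
                   class = "fp_expression"),
    F2 = structure(list(terms = list(), alpha = NA_real_),
                   class = "fp_expression"))
  rep1 <- posthoc_compare(truthm, zero, truth, g, n_sub = 60,
                          n_perm = 199, seed = 5)
  expect_identical(unname(rep1$rejections["bonferroni"]),
                   length(times) - 1L)
})
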