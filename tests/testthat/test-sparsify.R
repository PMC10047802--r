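# Term merging, design matrix, L2 selection, STRidge, retraining.

test_that("polynomial long division merges degenerate rational terms", {
  # u^2/(u + 0.001) on u in [0.5, 2]: main part u, remainder dropped
  num <- fracpde:::poly_var("u", 2)
  den <- fracpde:::poly_add(fracpde:::poly_var("u"),
                            fracpde:::poly_const(0.001))
  expr <- structure(list(terms = list(
    fracpde:::fp_term(1, ratio = list(num = num, den = den, var = "u"))),
    alpha = NA_real_), class = "fp_expression")
  merged <- merge_terms(expr, eps_merge = 0.01,
                        ranges = list(u = c(0.5, 2), v = c(0.5, 2)))
  expect_length(merged$terms, 1)
  expect_null(merged$terms[[1]]$ratio)
  expect_identical(names(merged$terms[[1]]$pow), "u")
  expect_equal(merged$terms[[1]]$coef, 1, tolerance = 1e-12)

  # u v / (v + 0.001) -> u (perturbation dropped)
  expr2 <- structure(list(terms = list(
    fracpde:::fp_term(1, ratio = list(
      num = fracpde:::poly_mul(fracpde:::poly_var("u"),
                               fracpde:::poly_var("v")),
      den = fracpde:::poly_add(fracpde:::poly_var("v"),
                               fracpde:::poly_const(0.001)),
      var = "v"))), alpha = NA_real_), class = "fp_expression")
  merged2 <- merge_terms(expr2, eps_merge = 0.01,
                         ranges = list(u = c(0.5, 2), v = c(0.5, 2)))
  expect_length(merged2$terms, 1)
  expect_identical(names(merged2$terms[[1]]$pow), "u")

  # like monomials are collected; already-monomial expressions unchanged
  expr3 <- structure(list(terms = list(
    fracpde:::fp_term(0.4, c(u = 1L)),
    fracpde:::fp_term(0.6, c(u = 1L)),
    fracpde:::fp_term(2, c(v = 1L))), alpha = NA_real_),
    class = "fp_expression")
  merged3 <- merge_terms(expr3, eps_merge = 1e-6,
                         ranges = list(u = c(0.5, 2), v = c(0.5, 2)))
  cf <- sapply(merged3$terms, function(tm) tm$coef)
  lb <- sapply(merged3$terms, function(tm) fracpde:::mono_key(tm$pow))
  expect_equal(sort(cf), c(1, 2))
  expect_setequal(lb, c("u", "v"))

  # a genuinely proper fraction with sizable sup-norm is kept
  expr4 <- structure(list(terms = list(
    fracpde:::fp_term(1, ratio = list(
      num = fracpde:::poly_var("u"),
      den = fracpde:::poly_add(fracpde:::poly_var("v", 2),
                               fracpde:::poly_const(0.5)),
      var = "v"))), alpha = NA_real_), class = "fp_expression")
  merged4 <- merge_terms(expr4, eps_merge = 0.01,
                         ranges = list(u = c(0.5, 2), v = c(0.5, 2)))
  expect_length(fracpde:::ratio_terms(merged4), 1)
})

test_that("design matrix columns evaluate terms on observed samples", {
  ds <- tiny_dataset_1d(n = 16, K = 3, M = 2)
  ds$U[] <- 2; ds$V[] <- 1 + ds$V * 0   # u constant = 2
  expr <- structure(list(terms = list(fracpde:::fp_term(1, c(u = 1L))),
                         alpha = NA_real_), class = "fp_expression")
  dm <- build_design_matrix(expr, ds, target = "u")
  expect_true(all(dm$Theta[, 1] == 2))
  expect_true(all(dm$Ut == 0))

  # duplicate columns trigger the rank warning
  expr2 <- structure(list(terms = list(
    fracpde:::fp_term(1, c(u = 1L)), fracpde:::fp_term(2, c(u = 1L))),
    alpha = NA_real_), class = "fp_expression")
  ds2 <- tiny_dataset_1d(n = 16, K = 3, M = 2)
  expect_warning(build_design_matrix(expr2, ds2, "u"), "rank deficient")
})

test_that("least squares on the true term set recovers Eq-17 coefficients
          from noiseless data", {
  dat <- fixture("ex1_noiseless_small", function() {
    generate_example_data(1, nl = 0, seed = 11, NInit = 2, n_grid = 24,
                          NTime = 10, sizes = c(2, 0, 0))
  })
  # candidate terms: 1, u, v, uv/(u^2+0.25u+0.25), uxx, uyy
  den <- fracpde:::poly_add(fracpde:::poly_add(
    fracpde:::poly_var("u", 2),
    fracpde:::poly_scale(fracpde:::poly_var("u"), 0.25)),
    fracpde:::poly_const(0.25))
  terms <- list(
    fracpde:::fp_term(1),
    fracpde:::fp_term(1, c(u = 1L)),
    fracpde:::fp_term(1, c(v = 1L)),
    fracpde:::fp_term(1, ratio = list(
      num = fracpde:::poly_mul(fracpde:::poly_var("u"),
                               fracpde:::poly_var("v")),
      den = den, var = "u")),
    fracpde:::fp_term(1, c(uxx = 1L)),
    fracpde:::fp_term(1, c(uyy = 1L)))
  expr <- structure(list(terms = terms, alpha = NA_real_),
                    class = "fp_expression")
  dm <- build_design_matrix(expr, dat$train, target = "u")
  cf <- qr.coef(qr(dm$Theta), dm$Ut)
  # truth: 1, -1, 0, -0.5, 0.3, 0.3 up to O(dt) + O(dx^2)
  expect_lt(max(abs(unname(cf) - c(1, -1, 0, -0.5, 0.3, 0.3))), 0.25)
})

test_that("L2-norm selection weights coefficients by column norm", {
  g <- fp_grid(c(0, 1), 10, dim = 1)
  mk <- function(Theta, labels) {
    structure(list(Theta = Theta, Ut = rnorm(nrow(Theta)),
                   terms = replicate(ncol(Theta),
                                     fracpde:::fp_term(1, c(u = 1L)),
                                     simplify = FALSE),
                   labels = labels, grid = g), class = "fp_design")
  }
  # orthonormal columns, tiny second coefficient: removed at delta = 0.1
  Q <- qr.Q(qr(matrix(rnorm(40), 20)))
  dm <- mk(Q, c("a", "b"))
  sel <- l2_select(dm, c(1, 1e-6), delta = 0.1)
  expect_identical(sel$keep, c(TRUE, FALSE))
  # delta -> 0 keeps everything
  sel0 <- l2_select(dm, c(1, 1e-6), delta = 1e-12)
  expect_true(all(sel0$keep))
  # norm weighting: xi = (0.01, 1) with norms (10, 0.1) gives equal eta
  Th <- cbind(rep(10 / sqrt(20), 20), rep(0.1 / sqrt(20), 20))
  dm2 <- mk(Th, c("big", "small"))
  sel2 <- l2_select(dm2, c(0.01, 1), delta = 0.05)
  expect_true(all(sel2$keep))
  expect_equal(sel2$eta[1], sel2$eta[2], tolerance = 1e-12)
  # scale equivariance: rescaling a column and its coefficient inversely
  # leaves the kept set unchanged
  dm3 <- mk(cbind(Q[, 1] * 50, Q[, 2]), c("a", "b"))
  sel3 <- l2_select(dm3, c(1 / 50, 1e-6), delta = 0.1)
  expect_identical(sel3$keep, sel$keep)
})

test_that("STRidge recovers exact sparse supports", {
  withr::with_seed(5, {
    Theta <- matrix(rnorm(200), 100, 2)
    Ut <- 3 * Theta[, 1]
  })
  xi <- stridge(Theta, Ut, lambda = 0, tol = 0.1)
  expect_equal(xi, c(3, 0), tolerance = 1e-10)
  # tol = 0: plain ridge solution, nothing thresholded
  xi0 <- stridge(Theta, Ut, lambda = 1e-8, tol = 0)
  expect_equal(xi0[1], 3, tolerance = 1e-5)
  # tol larger than everything: zero vector with a warning
  expect_warning(xiz <- stridge(Theta, Ut, lambda = 0, tol = 100),
                 "below tol")
  expect_identical(xiz, c(0, 0))
})

test_that("STRidge support is exact over seeds with mild noise", {
  # 200 x 8 design, 3 true nonzero coefficients, 1% noise
  ok_support <- 0; worst_coef <- 0
  true_xi <- c(1.5, 0, -2, 0, 0, 0.8, 0, 0)
  for (s in 1:20) {
    withr::with_seed(s, {
      Theta <- matrix(rnorm(200 * 8), 200, 8)
      y <- drop(Theta %*% true_xi)
      y <- y + rnorm(200, sd = 0.01 * stats::sd(y))
    })
    xi <- stridge(Theta, y, lambda = 1e-5, tol = 0.05, iters = 10)
    if (identical(which(xi != 0), which(true_xi != 0))) {
      ok_support <- ok_support + 1
      worst_coef <- max(worst_coef,
                        max(abs(xi[true_xi != 0] / true_xi[true_xi != 0] - 1)))
    }
  }
  expect_identical(ok_support, 20)
  expect_lt(worst_coef, 0.05)
})

test_that("STRidge support never grows across recursion", {
  withr::with_seed(9, {
    Theta <- matrix(rnorm(300), 60, 5)
    y <- Theta %*% c(2, 0.2, 0.04, 0, 0) + rnorm(60, sd = 0.05)
  })
  supports <- list()
  for (tol in c(0.01, 0.1, 0.5)) {
    xi <- stridge(Theta, drop(y), lambda = 1e-6, tol = tol)
    supports[[length(supports) + 1]] <- which(xi != 0)
  }
  expect_true(all(supports[[2]] %in% supports[[1]]))
  expect_true(all(supports[[3]] %in% supports[[2]]))
})

test_that("sparsify_model keeps the true support on noiseless data", {
  dat <- fixture("ex1_noiseless_small", function() {
    generate_example_data(1, nl = 0, seed = 11, NInit = 2, n_grid = 24,
                          NTime = 10, sizes = c(2, 0, 0))
  })
  den <- fracpde:::poly_add(fracpde:::poly_add(
    fracpde:::poly_var("u", 2),
    fracpde:::poly_scale(fracpde:::poly_var("u"), 0.25)),
    fracpde:::poly_const(0.25))
  # true terms with near-true coefficients plus small decoys
  terms <- list(
    fracpde:::fp_term(0.3, c(uxx = 1L)),
    fracpde:::fp_term(0.3, c(uyy = 1L)),
    fracpde:::fp_term(1),
    fracpde:::fp_term(-1, c(u = 1L)),
    fracpde:::fp_term(-0.5, ratio = list(
      num = fracpde:::poly_mul(fracpde:::poly_var("u"),
                               fracpde:::poly_var("v")),
      den = den, var = "u")),
    fracpde:::fp_term(0.003, c(v = 1L)),
    fracpde:::fp_term(-0.002, c(u = 1L, v = 1L)),
    fracpde:::fp_term(0.004, c(v = 2L)))
  expr <- structure(list(terms = terms, alpha = NA_real_),
                    class = "fp_expression")
  out <- sparsify_model(expr, dat$train, target = "u", delta = 0.05,
                        lambda = 1e-5, tol = 0.05)
  labs <- vapply(out$terms, fracpde:::term_label, "")
  expect_setequal(labs[!grepl("/", labs)], c("uxx", "uyy", "1", "u"))
  expect_length(fracpde:::ratio_terms(out), 1)
  # single-term expression survives with its least-squares coefficient
  one <- structure(list(terms = list(fracpde:::fp_term(5, c(u = 1L))),
                        alpha = NA_real_), class = "fp_expression")
  out1 <- sparsify_model(one, dat$train, target = "u", delta = 0.05,
                         lambda = 0, tol = 1e-6)
  expect_length(out1$terms, 1)
})
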