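# Constrained convolutional derivative operators and their moment algebra.

test_that("moment transform is the exact inverse of kernel construction", {
  withr::with_seed(1, {
    q2 <- matrix(rnorm(25), 5, 5)
    q1 <- rnorm(9)
  })
  expect_equal(filter_from_moments(moments_from_filter(q2)), q2,
               tolerance = 1e-10)
  expect_equal(filter_from_moments(moments_from_filter(q1)), q1,
               tolerance = 1e-10)

  # centered delta has m00 = 1 and no other moments
  qd <- matrix(0, 3, 3); qd[2, 2] <- 1
  M <- moments_from_filter(qd)
  expect_equal(M[1, 1], 1)
  expect_equal(sum(abs(M)) - 1, 0)

  # central difference along x: m10 = 1, m00 = m20 = 0
  qc <- matrix(0, 3, 3); qc[3, 2] <- 1 / 2; qc[1, 2] <- -1 / 2
  Mc <- moments_from_filter(qc)
  expect_equal(Mc[2, 1], 1)
  expect_equal(Mc[1, 1], 0)
  expect_equal(Mc[3, 1], 0)

  # moment matrix with only m00 = 1 gives back the delta kernel
  M0 <- matrix(0, 3, 3); M0[1, 1] <- 1
  expect_equal(filter_from_moments(M0), qd, tolerance = 1e-12)

  # m10 = 1 only: convolving a linear ramp returns dx * 1
  M1 <- matrix(0, 3, 3); M1[2, 1] <- 1
  q10 <- filter_from_moments(M1)
  dx <- 0.5
  ramp <- outer(dx * (1:10), rep(1, 10))
  inner <- fracpde:::conv2d_mirror(array(ramp, c(10, 10, 1)), q10)[3:8, 3:8, 1]
  expect_equal(inner, matrix(dx, 6, 6), tolerance = 1e-12)
})

test_that("banks expose the stated trainable parameter counts", {
  bank2 <- fp_filter_bank(2, 5, list(c(0, 0), c(2, 0), c(0, 2)), dx = 10 / 64)
  expect_identical(bank_n_params(bank2), 52L)
  bank1 <- fp_filter_bank(1, 19, list(0, 1, 2), dx = 5 * pi / 200,
                          frozen = list(1))
  expect_identical(bank_n_params(bank1), 32L)
})

test_that("constrained filters keep fixed moments and reach order >= 2", {
  bank <- fp_filter_bank(2, 5, list(c(0, 0), c(2, 0), c(0, 2)), dx = 10 / 32)
  withr::with_seed(7, {
    th <- rnorm(bank_n_params(bank), sd = 0.2)
  })
  bank <- fracpde:::bank_set_theta(bank, th)
  for (nm in names(bank$filters)) {
    f <- bank$filters[[nm]]
    M <- fracpde:::bank_moments(bank, nm)
    # fixed entries identical to the constraint pattern
    expect_identical(M[!f$free], f$M0[!f$free])
    # and realized by the kernel to near machine precision
    Mq <- moments_from_filter(fracpde:::bank_kernel(bank, nm))
    expect_lt(max(abs(Mq[!f$free] - f$M0[!f$free])), 1e-9)
  }

  # empirical convergence order on a smooth mirror-compatible field
  # (zero normal derivative at the boundary), three refinements
  w <- pi / 5
  for (nm in c("D20", "D02", "D00")) {
    ord <- bank$filters[[nm]]$order
    errs <- vapply(c(32, 64, 128), function(n) {
      g <- fp_grid(c(-5, 5), n, dim = 2)
      bk <- fp_filter_bank(2, 5, list(c(0, 0), c(2, 0), c(0, 2)), g$dx)
      bk <- fracpde:::bank_set_theta(bk, th)  # same random free moments
      fld <- outer(cos(w * (g$x + 5)), cos(w * (g$y + 5)))
      truth <- if (identical(ord, c(2, 0)) || identical(ord, c(0, 2)))
        -w^2 * fld else fld
      max(abs(apply_derivative(bk, ord, fld) - truth))
    }, 0)
    order1 <- log2(errs[1] / errs[2])
    order2 <- log2(errs[2] / errs[3])
    expect_gt(min(order1, order2), 1.9)
  }
})

test_that("derivative filters are exact on low-order polynomials", {
  g <- fp_grid(c(-5, 5), 24, dim = 2)
  bank <- fp_filter_bank(2, 3, list(c(1, 0)), g$dx)
  lin <- outer(g$x, rep(1, 24))
  d10 <- apply_derivative(bank, c(1, 0), lin)
  expect_equal(d10[3:22, 3:22], matrix(1, 20, 20), tolerance = 1e-10)

  bank2 <- fp_filter_bank(2, 5, list(c(2, 0)), g$dx)
  cst <- matrix(3.7, 24, 24)
  expect_equal(apply_derivative(bank2, c(2, 0), cst), matrix(0, 24, 24),
               tolerance = 1e-10)
})

test_that("the integral channel matches closed-form quadrature", {
  g <- fp_grid(c(-2.5 * pi, 2.5 * pi), 200, dim = 1)
  expect_equal(integral_operator(rep(2.5, 200), g), 2.5 * 5 * pi,
               tolerance = 1e-12)
  expect_lt(abs(integral_operator(sin(g$x), g)), 1e-10)
  g2 <- fp_grid(c(-1, 1), 201, dim = 1)
  expect_equal(integral_operator(g2$x^2, g2), 2 / 3, tolerance = 1e-4)
})

test_that("mirror-padded convolution conserves mass under pure diffusion", {
  # the even-reflection boundary is the discrete no-flux condition: a pure
  # diffusion step changes no total mass
  g <- fp_grid(c(-5, 5), 32, dim = 2)
  withr::with_seed(3, u <- matrix(runif(32 * 32), 32))
  du <- fracpde:::lap2d(u, g$dx)
  expect_lt(abs(sum(du)) / sum(abs(u)), 1e-12)
})
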