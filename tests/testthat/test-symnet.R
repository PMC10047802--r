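# Symbolic network: forward pass, masks, exponent, exact expansion.

worked_lib <- function(u, v, extra = NULL) {
  z <- 0 * u
  lib <- list(u = u, ux = z, uxx = z, v = v, vx = z, vxx = z,
              u2 = u^2, v2 = v^2, ua = u^1.5, I = z + 1)
  if (!is.null(extra)) lib[names(extra)] <- extra
  lib
}

test_that("the worked five-layer example evaluates and expands exactly", {
  net <- symnet_worked_example()
  out <- symnet_forward(net, worked_lib(rep(1, 3), rep(1, 3)))
  # hand evaluation: 0.1 + 6 + 6 + 2*(0.2*3/11) + 3*0.25
  expect_equal(out[1], 0.1 + 6 + 6 + 0.4 * 3 / 11 + 0.75, tolerance = 1e-12)

  ex <- symnet_to_expression(net)
  expect_identical(coef_of(ex, "uxx"), 0.3)
  expect_identical(coef_of(ex, "u"), 1.1)
  expect_identical(coef_of(ex, "v"), 7)
  expect_identical(coef_of(ex, "u^2"), 1)
  expect_identical(coef_of(ex, "u*v"), 2)
  expect_identical(coef_of(ex, "v^2"), 1)
  rt <- fracpde:::ratio_terms(ex)
  expect_length(rt, 2)
  expect_equal(sort(vapply(rt, function(tm) tm$coef, 0)), c(0.4, 0.6))
})

test_that("trivial networks behave as expected", {
  net <- symnet_config_demo()   # all weights zero
  u <- runif(5, 0.5, 1.5)
  expect_equal(as.numeric(symnet_forward(net, worked_lib(u, u))), rep(0, 5))
  expect_length(symnet_to_expression(net)$terms, 0)

  # identity routing: output = 1 * u
  net2 <- fracpde:::symnet_set_weights(net, Wout = c(1, rep(0, 14)))
  expect_equal(as.numeric(symnet_forward(net2, worked_lib(u, 0 * u))), u)
})

test_that("the exponent reparameterization stays inside [1, 2]", {
  expect_identical(alpha_from_eta(0), 1.5)
  expect_equal(alpha_from_eta(pi / 2), 2)
  etas <- seq(-50, 50, length.out = 401)
  expect_true(all(alpha_from_eta(etas) >= 1 & alpha_from_eta(etas) <= 2))
})

test_that("benchmark wirings reproduce the stated parameter counts", {
  g2 <- fp_grid(c(-5, 5), 16, dim = 2)
  m1 <- fracpde_model(1, g2, dt = 0.01)
  expect_identical(count_parameters(m1), 56L)
  expect_identical(bank_n_params(m1$bank), 52L)

  g1 <- fp_grid(c(-2.5 * pi, 2.5 * pi), 20, dim = 1)
  m2 <- fracpde_model(2, g1, dt = 0.05)
  expect_identical(count_parameters(m2), 29L)
  expect_identical(bank_n_params(m2$bank), 32L)

  # a fully masked network has no trainable weights
  ch <- c("u", "v")
  net0 <- fp_symnet(ch, "mul", list(matrix(FALSE, 2, 2)),
                    list(c(FALSE, FALSE)), c(FALSE, FALSE, FALSE),
                    mask_bout = FALSE, dim = 1)
  expect_identical(count_parameters(net0), 0L)
})

test_that("masked weights stay exactly zero through parameter round trips", {
  nets <- symnet_config_example2()
  net <- nets$net1
  th <- runif(length(fracpde:::symnet_get_params(net)), -1, 1)
  net <- fracpde:::symnet_set_params(net, th)
  for (i in seq_along(net$units)) {
    expect_true(all(net$W[[i]][!net$mask_W[[i]]] == 0))
    expect_true(all(net$b[[i]][!net$mask_b[[i]]] == 0))
  }
  expect_true(all(net$Wout[!net$mask_out] == 0))
  expect_identical(fracpde:::symnet_get_params(net), th)
})

test_that("expansion matches the forward pass on random draws", {
  # property: |expression(lib) - forward(lib)| tiny pointwise, away from
  # the division safeguard
  net0 <- symnet_config_demo()
  npar <- length(fracpde:::symnet_get_params(net0))
  worst <- 0
  for (rep in 1:40) {
    withr::with_seed(1000 + rep, {
      th <- rnorm(npar, sd = 0.3)
      u <- runif(40, 0.5, 2)
      v <- runif(40, 0.5, 2)
    })
    net <- fracpde:::symnet_set_params(net0, th)
    # draw depth-one wirings (units read channels only): deep chaining is
    # covered exactly by the worked example, and products of several random
    # rational units make the expanded form combinatorially large
    for (i in seq_along(net$units)) {
      if (i > 1) {
        w <- net$W[[i]]
        w[, 10 + seq_len(i - 1)] <- 0
        net$W[[i]] <- w
      }
    }
    lib <- worked_lib(u, v, extra = list(ux = runif(40), vx = runif(40),
                                         uxx = runif(40), vxx = runif(40),
                                         I = rep(runif(1), 40)))
    fw <- symnet_forward(net, lib, want_cache = TRUE)
    # points where every division denominator is clear of the safeguard
    ok <- rep(TRUE, 40)
    for (i in seq_along(net$units)) {
      if (net$units[i] == "div") ok <- ok & abs(fw$cache$xis[[i]]) > 1e-3
    }
    if (!any(ok)) next
    ex <- symnet_to_expression(net, prune_tol = 0)
    ev <- expression_eval(ex, lib[c("u", "ux", "uxx", "v", "vx", "vxx",
                                    "ua", "I")])
    worst <- max(worst, max(abs((ev - fw$out)[ok])))
  }
  expect_lt(worst, 1e-8)
})
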