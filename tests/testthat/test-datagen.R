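# Benchmark simulators, random initial conditions, noise and splitting.

test_that("random initial conditions are deterministic and max-normalized", {
  g <- fp_grid(c(-5, 5), 32, dim = 2)
  a <- random_initial_condition(g, seed = 7)
  b <- random_initial_condition(g, seed = 7)
  expect_identical(a, b)
  cc <- random_initial_condition(g, seed = 8)
  expect_false(identical(a$u0, cc$u0))
  # u0 = w0/max|w0| + c1: the centered field attains magnitude 1 exactly
  spread_u <- max(a$u0) - min(a$u0)
  expect_lte(spread_u, 2)
  expect_gt(spread_u, 0.5)   # multi-mode fields are not near-constant
  # v0 offset is positive
  expect_gt(mean(cc$v0), 0)
})

test_that("2-D simulator agrees with hand evaluation and an ODE oracle", {
  sys <- example1_system()
  g <- fp_grid(c(-5, 5), 16, dim = 2)
  z <- matrix(0, 16, 16)
  dt <- 1 / 1600
  tr <- simulate_true_2d(sys, z, z, g, dt, 2 * dt)
  # from u = v = 0 the interaction vanishes: one step gives dt*(1, 0.4)
  expect_equal(max(abs(tr$U[, , 2] - dt * 1)), 0, tolerance = 1e-5)
  expect_equal(max(abs(tr$V[, , 2] - dt * 0.4)), 0, tolerance = 1e-6)

  # spatially uniform states stay uniform and match a deSolve integration
  # of the reaction ODE (independent oracle)
  u0 <- matrix(0.7, 16, 16); v0 <- matrix(1.2, 16, 16)
  tr2 <- simulate_true_2d(sys, u0, v0, g, dt, 0.05)
  expect_equal(stats::sd(tr2$U[, , dim(tr2$U)[3]]), 0, tolerance = 1e-12)
  ode <- deSolve::ode(
    y = c(u = 0.7, v = 1.2), times = c(0, 0.05),
    func = function(t, y, p) {
      r <- sys$reaction(y[1], y[2])
      list(c(r$f1, r$f2))
    }, parms = NULL, method = "ode45")
  expect_equal(tr2$U[1, 1, dim(tr2$U)[3]], unname(ode[2, "u"]),
               tolerance = 1e-6)
  expect_equal(tr2$V[1, 1, dim(tr2$V)[3]], unname(ode[2, "v"]),
               tolerance = 1e-6)
})

test_that("the time integrator has second-order convergence on the ODE
          reduction", {
  sys <- example1_system()
  g <- fp_grid(c(-5, 5), 4, dim = 2)
  u0 <- matrix(0.7, 4, 4); v0 <- matrix(1.2, 4, 4)
  ref <- simulate_true_2d(sys, u0, v0, g, 1e-4, 0.1)
  endu <- function(tr) tr$U[1, 1, dim(tr$U)[3]]
  e1 <- abs(endu(simulate_true_2d(sys, u0, v0, g, 0.01, 0.1)) - endu(ref))
  e2 <- abs(endu(simulate_true_2d(sys, u0, v0, g, 0.005, 0.1)) - endu(ref))
  expect_gt(e1 / e2, 3)
  expect_lt(e1 / e2, 5)
})

test_that("the implicit 1-D solver matches closed forms", {
  # linear-only system: v_t = 10 v_xx - 0.4 v from uniform v0 = 1
  sys <- example2_system()
  sys$reaction <- function(u, v, grid) list(f1 = 0 * u, f2 = -0.4 * v)
  g <- fp_grid(c(-2.5 * pi, 2.5 * pi), 120, dim = 1)
  tr <- simulate_true_1d(sys, rep(0, 120), rep(1, 120), g, 0.01, 0.5,
                         restrict = 3)
  expect_equal(tr$V[20, ncol(tr$V)], exp(-0.2), tolerance = 2e-3)
  # restriction of a constant stays that constant
  expect_equal(tr$V[, 1], rep(1, 40))
  # trapezoid on a constant: integral of uniform u over [-2.5pi, 2.5pi]
  expect_equal(integral_operator(rep(0.3, 120), g), 0.3 * 5 * pi,
               tolerance = 1e-12)
})

test_that("a 2x-refined 2-D simulation matches after restriction", {
  sys <- example1_system()
  ic_fun <- function(x, y) {
    list(u = 0.4 + 0.2 * outer(cos(x), cos(y)),
         v = 1.0 + 0.2 * outer(sin(x), sin(y)))
  }
  run <- function(n) {
    g <- fp_grid(c(-5, 5), n, dim = 2)
    ic <- ic_fun(g$x, g$y)
    simulate_true_2d(sys, ic$u, ic$v, g, 1 / 1600, 0.05)
  }
  coarse <- run(16); fine <- run(32)
  uc <- coarse$U[, , dim(coarse$U)[3]]
  uf <- fracpde:::restrict_2d_mean(fine$U[, , dim(fine$U)[3]], 2)
  expect_lt(max(abs(uc - uf)), 5 * (10 / 16)^2)  # O(dx^2)
})

test_that("noise has the prescribed level, reproducibility and clamping", {
  sys <- example1_system()
  g <- fp_grid(c(-5, 5), 24, dim = 2)
  ic <- random_initial_condition(g, seed = 3)
  tr <- simulate_true_2d(sys, ic$u0, ic$v0, g, 1 / 1600, 0.05)
  sp <- subsample_and_split(list(tr), g, 0.01, 5, c(1, 0, 0))
  ds <- sp$train

  expect_identical(add_noise(ds, 0, seed = 1)$U, ds$U_true)
  n1 <- add_noise(ds, 0.05, seed = 9)
  n2 <- add_noise(ds, 0.05, seed = 9)
  expect_identical(n1$U, n2$U)
  # sample sd of the perturbation ~ nl * sd(truth)
  resid <- n1$U - ds$U_true
  expect_equal(stats::sd(as.numeric(resid)),
               0.05 * stats::sd(as.numeric(ds$U_true)),
               tolerance = 0.05)
  # absolute-value clamp leaves no negative values
  neg <- ds; neg$U_true <- -abs(neg$U_true); neg$U <- neg$U_true
  na <- add_noise(neg, 0.5, seed = 2, take_abs = TRUE)
  expect_gte(min(na$U), 0)
})

test_that("subsampling keeps every k-th snapshot and splits by index", {
  sys <- example1_system()
  g <- fp_grid(c(-5, 5), 8, dim = 2)
  trs <- lapply(1:3, function(j) {
    ic <- random_initial_condition(g, seed = j)
    simulate_true_2d(sys, ic$u0, ic$v0, g, 1 / 1600, 0.02)
  })
  # dt_obs = 0.01 over a 1/1600 fine step keeps every 16th snapshot
  sp <- subsample_and_split(trs, g, 0.01, 2, c(2, 1, 0))
  expect_identical(sp$train$M, 2L)
  expect_identical(sp$valid$M, 1L)
  expect_identical(sp$test$M, 0L)
  expect_equal(sp$train$U[, , 2, 1], trs[[1]]$U[, , 17])
  expect_equal(sp$valid$U[, , 3, 1], trs[[3]]$U[, , 33])
  # all trajectories into train
  sp2 <- subsample_and_split(trs, g, 0.01, 2, c(3, 0, 0))
  expect_identical(sp2$train$M, 3L)
  # identity subsampling when dt matches the fine step
  sp3 <- subsample_and_split(trs[1], g, 1 / 1600, 3, c(1, 0, 0))
  expect_equal(sp3$train$U[, , 2, 1], trs[[1]]$U[, , 2])
  expect_error(subsample_and_split(trs, g, 0.0105, 2, c(3, 0, 0)),
               "integer multiple")
})
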