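# Rollout, loss components, exact gradients, curriculum training.

test_that("Huber loss matches its closed form and is continuous", {
  expect_identical(huber(2, 1), 1.5)
  expect_identical(huber(0.5, 1), 0.125)
  s <- 0.37
  expect_equal(huber(s - 1e-12, s), huber(s + 1e-12, s), tolerance = 1e-9)
  expect_equal(huber(s, s), s / 2)
})

test_that("rollout reduces to closed forms for trivial right-hand sides", {
  g <- fp_grid(c(-2.5 * pi, 2.5 * pi), 20, dim = 1)
  m <- fracpde_model(2, g, dt = 0.05)
  m <- fracpde:::model_set_params(m, fracpde:::model_init_params(m, 1) * 0)
  u0 <- matrix(runif(20, 0.2, 1), ncol = 1)
  v0 <- matrix(runif(20, 0.2, 1), ncol = 1)
  # all-zero network: state constant
  r <- rollout(m, u0, v0, n_blocks = 3)
  expect_identical(r$U[[3]], u0)
  # constant right-hand side c: u_k = u0 + k dt c
  th <- fracpde:::model_init_params(m, 1) * 0
  nb <- length(fracpde:::bank_get_theta(m$bank))
  n1 <- length(fracpde:::symnet_get_params(m$net1))
  th[nb + n1] <- 0.7          # net1 output bias
  m2 <- fracpde:::model_set_params(m, th)
  r2 <- rollout(m2, u0, v0, n_blocks = 4)
  expect_equal(r2$U[[4]], u0 + 4 * 0.05 * 0.7, tolerance = 1e-12)
  expect_equal(r2$V[[4]], v0, tolerance = 1e-12)
})

test_that("the data loss matches a hand computation and the component
          split is exact", {
  # single trajectory, single teacher block, zero right-hand side:
  # Ldata = dx * sum(delta^2) / dt^2 for each field offset delta
  g <- fp_grid(c(0, 1), 10, dim = 1)
  U <- array(0.5, c(10, 2, 1)); V <- array(1, c(10, 2, 1))
  U[, 2, ] <- 0.5 + 0.02  # constant offset between consecutive blocks
  ds <- structure(list(grid = g, dt = 0.1, K = 1, M = 1,
                       U = U, V = V, U_true = U, V_true = V, nl = 0),
                  class = "fp_dataset")
  m <- fracpde_model(2, fp_grid(c(0, 1), 10, dim = 1), dt = 0.1)
  th0 <- fracpde:::model_init_params(m, 1) * 0
  cfg <- loss_config(n_blocks = 1, rollout = "teacher", pen_div = 0)
  lg <- fracpde:::loss_and_grad(th0, m, ds, cfg, want_grad = FALSE)
  expect_equal(lg$Ldata, g$dx * 10 * 0.02^2 / 0.1^2, tolerance = 1e-12)
  # lambda_M = lambda_S = 0: total equals Ldata (no division activity)
  expect_equal(lg$total, lg$Ldata, tolerance = 1e-15)
  # with regularization the components add exactly
  withr::with_seed(2, th <- th0 + rnorm(length(th0), sd = 0.05))
  cfg2 <- loss_config(lambda_M = 0.3, lambda_S = 0.7, n_blocks = 1,
                      rollout = "teacher", pen_div = 0)
  l2 <- fracpde:::loss_and_grad(th, m, ds, cfg2, want_grad = FALSE)
  expect_equal(l2$total, l2$Ldata + 0.3 * l2$Lmoment + 0.7 * l2$LSymNet,
               tolerance = 1e-12)
})

test_that("reverse-mode gradients agree with finite differences", {
  # The check point is well scaled: the observations are a short rollout
  # of the model itself plus a small perturbation, so the objective is
  # O(1e-2) and central differences are meaningful at relative 1e-5.
  # The FD reference is computed at two step sizes and each coordinate is
  # compared against the closer one (each coordinate has its own optimal
  # step).
  mk <- function(ds, ex, seed) {
    m <- fracpde_model(ex, ds$grid, dt = ds$dt)
    th0 <- fracpde:::model_init_params(m, seed = seed, sd = 0.02)
    m0 <- fracpde:::model_set_params(m, th0)
    nd <- length(dim(ds$U))
    U0 <- if (nd == 3) ds$U[, 1, ] else ds$U[, , 1, ]
    V0 <- if (nd == 3) ds$V[, 1, ] else ds$V[, , 1, ]
    r <- rollout(m0, U0, V0, n_blocks = ds$K, dt = ds$dt)
    withr::with_seed(seed + 9, {
      for (k in seq_len(ds$K)) {
        nz <- function(x) x + rnorm(length(x), sd = 1e-3)
        if (nd == 3) {
          ds$U[, k + 1, ] <- nz(r$U[[k]]); ds$V[, k + 1, ] <- nz(r$V[[k]])
        } else {
          ds$U[, , k + 1, ] <- nz(r$U[[k]]); ds$V[, , k + 1, ] <- nz(r$V[[k]])
        }
      }
      list(ds = ds, m = m, th = th0 + rnorm(length(th0), sd = 2e-3))
    })
  }
  check <- function(ds0, ex, cfg, seed) {
    mm <- mk(ds0, ex, seed)
    lg <- fracpde:::loss_and_grad(mm$th, mm$m, mm$ds, cfg)
    f <- function(t) fracpde:::loss_and_grad(t, mm$m, mm$ds, cfg,
                                             want_grad = FALSE)$total
    rel <- Inf
    for (h in c(1e-5, 1e-6)) {
      fd <- fd_gradient(f, mm$th, h = h)
      rel <- pmin(rel, abs(lg$grad - fd) /
                    pmax(abs(fd), abs(lg$grad), 1e-6))
    }
    max(rel)
  }
  # 1-D, teacher-forced with substeps
  cfg <- loss_config(lambda_M = 1e-4, lambda_S = 2e-4, n_blocks = 3,
                     pen_div = 1e-3, rollout = "teacher", n_substeps = 4)
  expect_lt(check(tiny_dataset_1d(), 2, cfg, 3), 1e-5)
  # 2-D, chained multi-step rollout
  cfg2 <- loss_config(lambda_M = 1e-4, lambda_S = 2e-4, n_blocks = 2,
                      pen_div = 1e-3, rollout = "multi")
  expect_lt(check(tiny_dataset_2d(), 1, cfg2, 5), 1e-5)
})

test_that("the compiled 1-D objective equals the reference implementation", {
  ds <- tiny_dataset_1d(n = 30, K = 5, M = 3)
  m <- fracpde_model(2, ds$grid, dt = ds$dt)
  cfg <- loss_config(lambda_M = 1e-5, lambda_S = 2e-5, n_blocks = 4,
                     pen_div = 1e-3, rollout = "teacher", n_substeps = 7)
  withr::with_seed(8,
    th <- fracpde:::model_init_params(m, seed = 3) + rnorm(61, sd = 0.03))
  ref <- withr::with_options(list(fracpde.use_compiled = FALSE),
                             fracpde:::loss_and_grad(th, m, ds, cfg))
  cpp <- withr::with_options(list(fracpde.use_compiled = TRUE),
                             fracpde:::loss_and_grad(th, m, ds, cfg))
  expect_equal(cpp$total, ref$total, tolerance = 1e-12)
  expect_equal(cpp$penalty, ref$penalty, tolerance = 1e-12)
  rel <- abs(cpp$grad - ref$grad) / pmax(abs(ref$grad), 1e-8)
  expect_lt(max(rel), 1e-8)
})

test_that("training is deterministic and does not regress from a perfect
          model on noiseless data", {
  dat <- fixture("ex2_tiny_noiseless", function() {
    generate_example_data(2, nl = 0, seed = 3, NInit = 2, n_grid = 40,
                          NTime = 5, sizes = c(2, 0, 0))
  })
  m <- fracpde_model(2, dat$grid, dt = dat$train$dt)
  cfg <- loss_config(lambda_M = 1e-7, lambda_S = 1e-6, n_blocks = 5,
                     rollout = "teacher", n_substeps = 25)
  t1 <- train(dat$train, cfg, m, K = 5, Nt = 5, seed = 2, maxit = 6,
              substeps = 25)
  t2 <- train(dat$train, cfg, m, K = 5, Nt = 5, seed = 2, maxit = 6,
              substeps = 25)
  expect_identical(t1$history$total, t2$history$total)
  expect_identical(fracpde:::model_get_params(t1$model),
                   fracpde:::model_get_params(t2$model))

  # starting from the true parameters, the loss never increases across
  # curriculum stages
  th_true <- example2_truth_theta(m)
  t3 <- train(dat$train, cfg, m, K = 5, Nt = 5, seed = 2, maxit = 10,
              substeps = 25, theta0 = th_true, warm_start = FALSE)
  expect_true(all(diff(t3$history$total) < 1e-6))
  expect_lt(t3$history$total[5],
            fracpde:::loss_and_grad(th_true, m, dat$train,
                                    loss_config(lambda_M = 1e-7,
                                                lambda_S = 1e-6,
                                                n_blocks = 5,
                                                rollout = "teacher",
                                                n_substeps = 25),
                                    want_grad = FALSE)$total * 1.001)
})

test_that("stronger weight regularization weakly shrinks the weights", {
  dat <- fixture("ex2_tiny_noiseless", function() {
    generate_example_data(2, nl = 0, seed = 3, NInit = 2, n_grid = 40,
                          NTime = 5, sizes = c(2, 0, 0))
  })
  m <- fracpde_model(2, dat$grid, dt = dat$train$dt)
  l1norm <- function(lS) {
    cfg <- loss_config(lambda_M = 1e-7, lambda_S = lS, n_blocks = 5,
                       rollout = "teacher", n_substeps = 10)
    tr <- train(dat$train, cfg, m, K = 5, Nt = 1, seed = 4, maxit = 60,
                substeps = 10)
    sum(abs(c(fracpde:::symnet_get_params(tr$model$net1),
              fracpde:::symnet_get_params(tr$model$net2))))
  }
  expect_lt(l1norm(1e-2), l1norm(1e-8) + 1e-8)
})

test_that("the expanding window uses the prescribed block counts", {
  dat <- fixture("ex2_tiny_noiseless", function() {
    generate_example_data(2, nl = 0, seed = 3, NInit = 2, n_grid = 40,
                          NTime = 5, sizes = c(2, 0, 0))
  })
  m <- fracpde_model(2, dat$grid, dt = dat$train$dt)
  cfg <- loss_config(n_blocks = 5, rollout = "teacher", n_substeps = 5)
  tr <- train(dat$train, cfg, m, K = 5, Nt = 5, seed = 1, maxit = 2,
              substeps = 5)
  expect_identical(tr$history$blocks, c(1, 2, 3, 4, 5))
})
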