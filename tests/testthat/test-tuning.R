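# Hyperparameter search over the expanding-window validation loss.

test_that("the search returns the sampled pair for a unit budget and
          approaches the optimum of a convex surrogate", {
  surrogate <- function(lM, lS) (log10(lM) + 5)^2 + (log10(lS) + 4)^2
  one <- tune(surrogate, budget = 1, seed = 2)
  expect_identical(nrow(one$trials), 1L)
  expect_identical(one$value, one$trials$value[1])

  res <- tune(surrogate, budget = 40, seed = 7)
  expect_lt(abs(log10(res$lambda_M) + 5), 1)
  expect_lt(abs(log10(res$lambda_S) + 4), 1)
  # monotone best-so-far
  best <- cummin(res$trials$value)
  expect_true(all(diff(best) <= 0))
  # reproducible trial sequence
  res2 <- tune(surrogate, budget = 40, seed = 7)
  expect_identical(res$trials, res2$trials)
  expect_error(tune(function(a, b) Inf, budget = 3, seed = 1),
               "non-finite")
})

test_that("expanding-window validation averages the staged losses", {
  dat <- fixture("ex2_tiny_noiseless", function() {
    generate_example_data(2, nl = 0, seed = 3, NInit = 2, n_grid = 40,
                          NTime = 5, sizes = c(2, 0, 0))
  })
  # build a one-trajectory validation set from the same conditions
  datv <- generate_example_data(2, nl = 0, seed = 4, NInit = 2, n_grid = 40,
                                NTime = 5, sizes = c(1, 1, 0))
  m <- fracpde_model(2, dat$grid, dt = dat$train$dt)
  avl <- expanding_validation_loss(
    1e-7, 1e-6, dat$train, datv$valid, m, K = 5, Nt = 5, seed = 1,
    rollout = "teacher", n_substeps = 10, maxit = 3, substeps = 10)
  expect_true(is.finite(avl))
  expect_gt(avl, 0)

  # Nt = 1 equals the single full-window validation loss of the same fit
  cfg <- loss_config(lambda_M = 1e-7, lambda_S = 1e-6, n_blocks = 5,
                     rollout = "teacher", n_substeps = 10)
  tr <- train(dat$train, cfg, m, K = 5, Nt = 1, seed = 1, maxit = 3,
              substeps = 10, valid_ds = datv$valid)
  avl1 <- expanding_validation_loss(
    1e-7, 1e-6, dat$train, datv$valid, m, K = 5, Nt = 1, seed = 1,
    rollout = "teacher", n_substeps = 10, maxit = 3, substeps = 10)
  expect_equal(avl1, tr$history$valid[1], tolerance = 1e-12)
})
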