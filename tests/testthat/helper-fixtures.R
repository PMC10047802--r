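# Small in-code fixtures shared across test files.

# Tiny synthetic dataset on an arbitrary smooth state (not a simulator
# output): enough structure for gradient and plumbing checks.
tiny_dataset_1d <- function(n = 24, K = 4, M = 2, seed = 42, dt = 0.05) {
  g <- fp_grid(c(-2.5 * pi, 2.5 * pi), n, dim = 1)
  withr::with_seed(seed, {
    U <- array(runif(n * (K + 1) * M, 0.2, 1.0), c(n, K + 1, M))
    V <- array(runif(n * (K + 1) * M, 0.4, 1.2), c(n, K + 1, M))
  })
  structure(list(grid = g, dt = dt, K = K, M = M,
                 U = U, V = V, U_true = U, V_true = V, nl = 0),
            class = "fp_dataset")
}

tiny_dataset_2d <- function(n = 12, K = 3, M = 2, seed = 42, dt = 0.02) {
  g <- fp_grid(c(-5, 5), n, dim = 2)
  withr::with_seed(seed, {
    U <- array(runif(n * n * (K + 1) * M, 0.3, 1.2), c(n, n, K + 1, M))
    V <- array(runif(n * n * (K + 1) * M, 0.5, 1.5), c(n, n, K + 1, M))
  })
  structure(list(grid = g, dt = dt, K = K, M = M,
                 U = U, V = V, U_true = U, V_true = V, nl = 0),
            class = "fp_dataset")
}

# Central-difference gradient of a scalar function.
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

# Model loaded with the true right-hand side of the 1-D benchmark
# (network weights set to reproduce Eq-21 exactly, kernels at the compact
# stencils).
example2_truth_theta <- function(model) {
  n1 <- model$net1
  n1$W[[1]][1, 4] <- 1; n1$W[[1]][2, 4] <- 1          # f1 = v * v
  n1$W[[2]][1, 1] <- 0.081                             # num: 0.081 u
  n1$W[[2]][2, 9] <- 1; n1$b[[2]] <- c(0, 0.0215)      # den: v^2 + 0.0215
  n1$W[[3]][1, 8] <- 1; n1$W[[3]][2, 7] <- -0.229      # ua * (-0.229 I)
  n1$Wout[] <- 0
  n1$Wout[3] <- 0.1; n1$Wout[1] <- -3.6; n1$Wout[8] <- 3.6
  n1$Wout[10] <- 1; n1$Wout[11] <- 1
  n2 <- model$net2
  n2$Wout[] <- 0
  n2$Wout[1] <- 1; n2$Wout[4] <- -0.4; n2$Wout[6] <- 10
  c(fracpde:::bank_init_theta(model$bank),
    fracpde:::symnet_get_params(n1),
    fracpde:::symnet_get_params(n2), 0)
}

# Shared slow fixtures, built lazily once per test run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# True 2-D benchmark right-hand side as a term-based sparse model.
true_ex1_sparse <- function() {
  den <- fracpde:::poly_add(fracpde:::poly_add(
    fracpde:::poly_var("u", 2),
    fracpde:::poly_scale(fracpde:::poly_var("u"), 0.25)),
    fracpde:::poly_const(0.25))
  rat <- function(cf) fracpde:::fp_term(cf, ratio = list(
    num = fracpde:::poly_mul(fracpde:::poly_var("u"),
                             fracpde:::poly_var("v")),
    den = den, var = "u"))
  list(
    F1 = structure(list(terms = list(
      fracpde:::fp_term(0.3, c(uxx = 1L)),
      fracpde:::fp_term(0.3, c(uyy = 1L)),
      fracpde:::fp_term(1),
      fracpde:::fp_term(-1, c(u = 1L)),
      rat(-0.5)), alpha = NA_real_), class = "fp_expression"),
    F2 = structure(list(terms = list(
      fracpde:::fp_term(0.4, c(vxx = 1L)),
      fracpde:::fp_term(0.4, c(vyy = 1L)),
      fracpde:::fp_term(0.4),
      fracpde:::fp_term(-0.2, c(v = 1L)),
      rat(-0.5)), alpha = NA_real_), class = "fp_expression"))
}

# True 1-D benchmark right-hand side as a term-based sparse model.
true_ex2_sparse <- function() {
  list(
    F1 = structure(list(terms = list(
      fracpde:::fp_term(0.1, c(uxx = 1L)),
      fracpde:::fp_term(3.6, c(ua = 1L)),
      fracpde:::fp_term(-3.6, c(u = 1L)),
      fracpde:::fp_term(-0.229, c(ua = 1L, I = 1L)),
      fracpde:::fp_term(0.081, ratio = list(
        num = fracpde:::poly_var("u"),
        den = fracpde:::poly_add(fracpde:::poly_var("v", 2),
                                 fracpde:::poly_const(0.0215)),
        var = "v"))), alpha = 1.5), class = "fp_expression"),
    F2 = structure(list(terms = list(
      fracpde:::fp_term(10, c(vxx = 1L)),
      fracpde:::fp_term(1, c(u = 1L)),
      fracpde:::fp_term(-0.4, c(v = 1L))), alpha = 1.5),
      class = "fp_expression"))
}

# Canonical term labels of a discovered equation, for structure checks.
structure_labels <- function(expr) {
  sort(vapply(expr$terms, function(tm) {
    if (!is.null(tm$ratio)) "rational" else fracpde:::mono_key(tm$pow)
  }, ""))
}
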