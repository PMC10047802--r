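## Training: forward-Euler Delta-t-block rollout of the learned dynamics,
## three-part loss (data + moment + network regularization), and L-BFGS
## optimization with an expanding-window curriculum.  Gradients are exact
## reverse-mode derivatives (back-propagation through time through the
## rollout, the symbolic network, and the constrained convolution kernels),
## validated against finite differences in the test suite.

#' Trainable model: filter bank + network pair
#'
#' Bundles the shared constrained filter bank, the two symbolic networks
#' (one per equation) and, when a `ua` channel is present, the shared
#' exponent parameter `eta` (`alpha = 1.5 + 0.5 sin(eta)`).
#'
#' @param example 1 (2-D benchmark wiring) or 2 (1-D benchmark wiring).
#' @param grid an [fp_grid()].
#' @param dt block time step of the rollout.
#' @param baseline polynomial-only configuration.
#' @return object of class `fp_nnmodel`.
#' @export
fracpde_model <- function(example, grid, dt, baseline = FALSE) {
  if (example == 1) {
    stopifnot(grid$dim == 2)
    bank <- fp_filter_bank(2, 5, list(c(0, 0), c(2, 0), c(0, 2)), grid$dx)
    nets <- symnet_config_example1(baseline)
  } else {
    stopifnot(grid$dim == 1)
    bank <- fp_filter_bank(1, 19, list(0, 1, 2), grid$dx, frozen = list(1))
    nets <- symnet_config_example2(baseline)
  }
  has_alpha <- any(c(nets$net1$channels, nets$net2$channels) == "ua")
  structure(list(grid = grid, dt = dt, bank = bank,
                 net1 = nets$net1, net2 = nets$net2,
                 eta = if (has_alpha) 0 else NULL),
            class = "fp_nnmodel")
}

#' @export
print.fp_nnmodel <- function(x, ...) {
  cat(sprintf("<fp_nnmodel %dD: %d network weights%s + %d moment entries>\n",
              x$grid$dim,
              symnet_n_params(x$net1) + symnet_n_params(x$net2),
              if (!is.null(x$eta)) " + eta" else "",
              bank_n_params(x$bank)))
  invisible(x)
}

#' Count trainable parameters
#'
#' For a network: unmasked weights and biases.  For a full model: both
#' networks plus the exponent parameter `eta` when present (the moment
#' entries of the filter bank are counted separately by
#' [bank_n_params()]).
#'
#' @param x an [fp_symnet()] or `fp_nnmodel`.
#' @return integer count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "fp_symnet")) return(symnet_n_params(x))
  stopifnot(inherits(x, "fp_nnmodel"))
  as.integer(symnet_n_params(x$net1) + symnet_n_params(x$net2) +
               (!is.null(x$eta)))
}

model_get_params <- function(model) {
  c(bank_get_theta(model$bank),
    symnet_get_params(model$net1),
    symnet_get_params(model$net2),
    model$eta)
}

model_set_params <- function(model, theta) {
  nb <- length(bank_get_theta(model$bank))
  n1 <- length(symnet_get_params(model$net1))
  n2 <- length(symnet_get_params(model$net2))
  stopifnot(length(theta) == nb + n1 + n2 + (!is.null(model$eta)))
  model$bank <- bank_set_theta(model$bank, theta[seq_len(nb)])
  model$net1 <- symnet_set_params(model$net1, theta[nb + seq_len(n1)])
  model$net2 <- symnet_set_params(model$net2, theta[nb + n1 + seq_len(n2)])
  if (!is.null(model$eta)) model$eta <- theta[nb + n1 + n2 + 1]
  model
}

# Random initialization: moment entries start at the embedded compact
# stencils (exact second-order kernels with minimal spectral response),
# network weights ~ N(0, sd^2), division-unit denominator biases centered
# at 1 (keeps initial denominators away from the safeguard), eta = 0
# (alpha starts at 1.5).
model_init_params <- function(model, seed, sd = 0.1) {
  with_seed(seed, {
    init_net <- function(net) {
      th <- stats::rnorm(length(symnet_get_params(net)), sd = sd)
      # locate the denominator bias of each division unit in the flat layout
      pos <- 0L
      for (i in seq_along(net$units)) {
        nw <- sum(net$mask_W[[i]])
        nb <- sum(net$mask_b[[i]])
        if (net$units[i] == "div" && nb == 2) th[pos + nw + 2L] <- th[pos + nw + 2L] + 1
        pos <- pos + nw + nb
      }
      th
    }
    c(bank_init_theta(model$bank),
      init_net(model$net1), init_net(model$net2),
      if (!is.null(model$eta)) 0)
  })
}

## ---- channel evaluation with cache --------------------------------------

model_deriv_names <- function(model) {
  specs <- c(model$net1$specs, model$net2$specs)
  out <- list()
  for (sp in model$net1$specs) out[[sp$name]] <- sp
  for (sp in model$net2$specs) out[[sp$name]] <- sp
  out
}

# Kernels of the bank, computed once per loss evaluation.  In 1-D the
# mirror-padded correlation is folded into a dense banded operator so each
# application is a single matrix product.
bank_kernels <- function(bank, n = NULL) {
  ks <- lapply(names(bank$filters), function(nm) bank_kernel(bank, nm))
  names(ks) <- names(bank$filters)
  out <- list(q = ks)
  if (bank$dim == 1 && !is.null(n)) {
    out$C <- lapply(ks, conv1d_operator, n = n)
  }
  out
}

# Dense n x n operator equivalent to mirror-pad + correlate with q.
conv1d_operator <- function(q, n) {
  N <- length(q); h <- (N - 1L) / 2L
  B <- matrix(0, n, n + 2L * h)
  idx <- cbind(rep(seq_len(n), N),
               rep(seq_len(n), N) + rep(0:(N - 1L), each = n))
  B[idx] <- rep(q, each = n)
  C <- B[, h + seq_len(n), drop = FALSE]
  C[, 1:h] <- C[, 1:h] + B[, h:1, drop = FALSE]
  C[, (n - h + 1):n] <- C[, (n - h + 1):n] +
    B[, (n + 2L * h):(n + h + 1L), drop = FALSE]
  C
}

deriv_key <- function(field, order) paste0("D", paste0(order, collapse = ""),
                                           "_", field)

# Forward evaluation of both right-hand sides at one state, with the cache
# needed for the backward pass.  U, V are batched arrays (trajectory last).
rhs_forward <- function(model, kern, U, V, want_cache = FALSE) {
  grid <- model$grid
  specs <- model_deriv_names(model)
  fields <- list(u = U, v = V)
  derivs <- list()
  for (sp in specs) {
    key <- if (sp$type == "deriv") deriv_key(sp$field, sp$order)
           else deriv_key(sp$field, rep(0, grid$dim))
    if (is.null(derivs[[key]])) {
      ord <- if (sp$type == "deriv") sp$order else rep(0, grid$dim)
      nm <- paste0("D", paste0(ord, collapse = ""))
      val <- if (grid$dim == 1) {
        if (!is.null(kern$C)) kern$C[[nm]] %*% fields[[sp$field]]
        else conv1d_mirror(fields[[sp$field]], kern$q[[nm]])
      } else conv2d_mirror(fields[[sp$field]], kern$q[[nm]])
      derivs[[key]] <- val / grid$dx^sum(ord)
    }
  }
  alpha <- if (!is.null(model$eta)) alpha_from_eta(model$eta) else NA_real_
  chan <- list()
  extras <- list()
  for (sp in specs) {
    if (!is.null(chan[[sp$name]])) next
    base <- derivs[[deriv_key(sp$field, rep(0, grid$dim))]]
    chan[[sp$name]] <- switch(sp$type,
      deriv = derivs[[deriv_key(sp$field, sp$order)]],
      square = base^2,
      power = {
        bpos <- pmax(base, 0)
        extras$pow_base <- bpos
        bpos^alpha
      },
      integral = {
        I <- grid$dx * colSums(base)
        matrix(I, nrow = nrow(base), ncol = length(I), byrow = TRUE)
      })
  }
  f1 <- symnet_forward(model$net1, chan, want_cache = TRUE)
  f2 <- symnet_forward(model$net2, chan, want_cache = TRUE)
  pen <- f1$cache$penalty + f2$cache$penalty
  if (!want_cache) return(list(F1 = f1$out, F2 = f2$out, penalty = pen))
  list(F1 = f1$out, F2 = f2$out, penalty = pen,
       cache = list(chan = chan, derivs = derivs, sn1 = f1$cache,
                    sn2 = f2$cache, alpha = alpha, extras = extras,
                    U = U, V = V,
                    penalty = pen))
}

# Reverse-mode pass of rhs_forward.  Returns the VJP w.r.t. the input state
# and accumulates parameter gradients into the environment `acc` (fields
# gq[[name]], g1, g2, geta).
rhs_backward <- function(model, kern, cache, gF1, gF2, acc, pen_w) {
  grid <- model$grid
  b1 <- symnet_backward(model$net1, cache$sn1, gF1, pen_w)
  b2 <- symnet_backward(model$net2, cache$sn2, gF2, pen_w)
  acc$g1 <- acc$g1 + symnet_flatten_grads(model$net1, b1)
  acc$g2 <- acc$g2 + symnet_flatten_grads(model$net2, b2)

  # merge channel gradients by name
  gchan <- list()
  for (i in seq_along(model$net1$channels)) {
    nm <- model$net1$channels[i]
    gchan[[nm]] <- b1$gchannels[[i]]
  }
  for (i in seq_along(model$net2$channels)) {
    nm <- model$net2$channels[i]
    gchan[[nm]] <- if (is.null(gchan[[nm]])) b2$gchannels[[i]]
                   else gchan[[nm]] + b2$gchannels[[i]]
  }

  # channel -> smoothed-derivative gradients
  gderiv <- list()
  add_deriv <- function(key, g) {
    gderiv[[key]] <<- if (is.null(gderiv[[key]])) g else gderiv[[key]] + g
  }
  specs <- model_deriv_names(model)
  for (sp in specs) {
    g <- gchan[[sp$name]]
    if (is.null(g)) next
    key0 <- deriv_key(sp$field, rep(0, grid$dim))
    base <- cache$derivs[[key0]]
    switch(sp$type,
      deriv = add_deriv(deriv_key(sp$field, sp$order), g),
      square = add_deriv(key0, 2 * base * g),
      power = {
        bpos <- cache$extras$pow_base
        alpha <- cache$alpha
        add_deriv(key0, g * alpha * bpos^(alpha - 1) * (base > 0))
        if (!is.null(model$eta)) {
          ok <- bpos > 0
          acc$geta <- acc$geta + 0.5 * cos(model$eta) *
            sum(g[ok] * bpos[ok]^alpha * log(bpos[ok]))
        }
      },
      integral = {
        gI <- grid$dx * colSums(g)
        add_deriv(key0, matrix(gI, nrow = nrow(base), ncol = length(gI),
                               byrow = TRUE))
      })
  }

  # smoothed derivatives -> state and kernel gradients
  gU <- 0 * cache$U; gV <- 0 * cache$V
  fields <- list(u = cache$U, v = cache$V)
  for (key in names(gderiv)) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    nm <- parts[1]; field <- parts[2]
    ordsum <- sum(as.integer(strsplit(substring(nm, 2), "")[[1]]))
    g <- gderiv[[key]] / grid$dx^ordsum
    if (grid$dim == 1) {
      gstate <- if (!is.null(kern$C)) crossprod(kern$C[[nm]], g)
                else conv1d_mirror_adj(g, kern$q[[nm]], grid$n)
      if (model$bank$filters[[nm]]$trainable)
        acc$gq[[nm]] <- acc$gq[[nm]] + conv1d_kernel_grad(g, fields[[field]],
                                                          model$bank$N)
    } else {
      gstate <- conv2d_mirror_adj(g, kern$q[[nm]], grid$n)
      if (model$bank$filters[[nm]]$trainable)
        acc$gq[[nm]] <- acc$gq[[nm]] + conv2d_kernel_grad(g, fields[[field]],
                                                          model$bank$N)
    }
    if (field == "u") gU <- gU + gstate else gV <- gV + gstate
  }
  list(gU = gU, gV = gV, penalty = cache$penalty)
}

## ---- rollout ------------------------------------------------------------

#' Multi-step forward-Euler rollout of the learned dynamics
#'
#' Starting from an observed snapshot, iterates
#' `state <- state + dt * SymNet(channels(state))`, recomputing every
#' library channel (derivatives via the trained kernels, integral, power)
#' from the current predicted state at each block.
#'
#' @param model an `fp_nnmodel`.
#' @param U0,V0 initial state (batched arrays, trajectory last; a single
#'   field works too).
#' @param n_blocks number of blocks.
#' @param dt block step (defaults to the model's).
#' @return `list(U, V, ok)`: lists of per-block states (`U[[k]]` after `k`
#'   blocks), and `ok = FALSE` if the state left the finite range (the
#'   rollout is then truncated).
#' @export
rollout <- function(model, U0, V0, n_blocks, dt = model$dt) {
  kern <- bank_kernels(model$bank, model$grid$n)
  U <- vector("list", n_blocks); V <- vector("list", n_blocks)
  u <- U0; v <- V0
  for (k in seq_len(n_blocks)) {
    r <- rhs_forward(model, kern, u, v)
    u <- u + dt * r$F1
    v <- v + dt * r$F2
    if (!all(is.finite(u)) && !all(is.finite(v)) ||
        any(!is.finite(u)) || any(!is.finite(v)))
      return(list(U = U[seq_len(k - 1)], V = V[seq_len(k - 1)], ok = FALSE))
    U[[k]] <- u; V[[k]] <- v
  }
  list(U = U, V = V, ok = TRUE)
}

## ---- loss ---------------------------------------------------------------

#' Huber loss
#'
#' `|x| - s/2` for `|x| > s`, `x^2 / (2s)` otherwise; continuous with
#' continuous first derivative at `|x| = s`.
#'
#' @param x numeric.
#' @param s positive threshold.
#' @return elementwise loss values.
#' @export
huber <- function(x, s) {
  stopifnot(s > 0)
  ifelse(abs(x) > s, abs(x) - s / 2, x^2 / (2 * s))
}

huber_grad <- function(x, s) ifelse(abs(x) > s, sign(x), x / s)

#' Loss configuration
#'
#' @param lambda_M,lambda_S nonnegative regularization weights on the free
#'   moment entries and on the network weights.
#' @param s Huber threshold (default 0.01).
#' @param n_blocks number of Delta-t blocks in the rollout.
#' @param pen_div weight of the division-safeguard penalty.
#' @param rollout `"multi"`: one chained rollout from the observed snapshot
#'   at block 0, compared against blocks `1..n` (the standard Delta-t-block
#'   construction); `"teacher"`: each block is predicted one observation
#'   step ahead from the previous *observed* snapshot (blocks independent).
#'   The teacher-forced form is the right choice whenever the chained
#'   rollout is dominated by stiff error growth rather than by model
#'   mismatch (the 1-D benchmark: diffusion number `d2 dt / dx^2` around
#'   80, where the chained explicit rollout diverges even at the true
#'   parameters).
#' @param n_substeps forward-Euler micro-steps per Delta-t block.  The
#'   block map remains forward Euler; sub-stepping keeps it stable and
#'   unbiased when the fastest diffusive mode relaxes faster than the
#'   observation step (choose `m > d_max * dt * lambda_max / 2`, with
#'   `lambda_max ~ 4/dx^2` in 1-D and `8/dx^2` in 2-D).
#' @return a list of class `fp_loss_cfg`.
#' @export
loss_config <- function(lambda_M = 0, lambda_S = 0, s = 0.01, n_blocks = 1,
                        pen_div = 1e-6, rollout = c("multi", "teacher"),
                        n_substeps = 1) {
  rollout <- match.arg(rollout)
  stopifnot(lambda_M >= 0, lambda_S >= 0, s > 0, n_blocks >= 1,
            n_substeps >= 1)
  structure(list(lambda_M = lambda_M, lambda_S = lambda_S, s = s,
                 n_blocks = n_blocks, pen_div = pen_div, rollout = rollout,
                 n_substeps = as.integer(n_substeps)),
            class = "fp_loss_cfg")
}

# Observed state of block k (0-based) for every trajectory, shaped with the
# trajectory batch as the trailing dimension.
ds_block <- function(ds, k, what = "U") {
  A <- ds[[what]]
  n <- ds$grid$n
  if (ds$grid$dim == 1)
    matrix(A[, k + 1, , drop = FALSE], nrow = n)
  else
    array(A[, , k + 1, , drop = FALSE], c(n, n, ds$M))
}

#' Rollout training loss with components
#'
#' `L = Ldata + lambda_M * Lmoment + lambda_S * LSymNet` where `Ldata` is
#' the mean squared discrete-L2 rollout error over blocks, trajectories and
#' both fields, scaled by `1 / (n N dt^2)`; `Lmoment` is the Huber penalty
#' over all free moment entries; `LSymNet` the Huber penalty over all
#' unmasked network weights.  The rollout starts from the observed snapshot
#' at block 0 of each trajectory and is compared against the observed
#' snapshots at blocks `1..n` (multi-step, shared parameters).
#'
#' @param model an `fp_nnmodel`.
#' @param ds an `fp_dataset` batch.
#' @param cfg a [loss_config()].
#' @return list with `total`, `Ldata`, `Lmoment`, `LSymNet`, `penalty`.
#' @export
loss_total <- function(model, ds, cfg) {
  lg <- loss_and_grad(model_get_params(model), model, ds, cfg,
                      want_grad = FALSE)
  lg[c("total", "Ldata", "Lmoment", "LSymNet", "penalty")]
}

# Soft state clip: identity for |x| <= c, smooth tanh saturation toward B
# beyond.  Applied after every micro-step with c well above the data range,
# it leaves feasible trajectories exactly unchanged while keeping diverging
# ones bounded with nonzero gradients -- the loss surface has no cliffs for
# the line search to fail on.
soft_clip <- function(x, c, B) {
  idx <- abs(x) > c
  if (any(idx)) {
    s <- sign(x[idx])
    x[idx] <- s * (c + (B - c) * tanh((abs(x[idx]) - c) / (B - c)))
  }
  x
}

soft_clip_grad <- function(x, c, B) {
  g <- rep(1, length(x))
  idx <- abs(x) > c
  if (any(idx)) g[idx] <- 1 / cosh((abs(x[idx]) - c) / (B - c))^2
  array(g, dim_of(x))
}

# Stack the per-block arrays of a dataset along the batch dimension:
# block-start states (blocks 0..n-1) and block-end targets (blocks 1..n).
stack_blocks <- function(ds, n, what) {
  pieces <- lapply(seq_len(n) - 1L, function(k) ds_block(ds, k, what))
  tgt <- lapply(seq_len(n), function(k) ds_block(ds, k, what))
  bind <- function(lst) {
    if (ds$grid$dim == 1) do.call(cbind, lst)
    else {
      nn <- ds$grid$n
      array(unlist(lst, use.names = FALSE), c(nn, nn, ds$M * n))
    }
  }
  list(start = bind(pieces), target = bind(tgt))
}

# Static description of the model for the compiled 1-D kernel: global
# channel table and per-net wiring in plain arrays.
build_cpp_plan <- function(model) {
  specs <- model_deriv_names(model)
  nms <- names(specs)
  code <- function(sp) {
    type <- match(sp$type, c("deriv", "square", "power", "integral")) - 1L
    filt <- if (sp$type == "deriv") as.integer(sp$order) else 0L
    c(type, if (sp$field == "u") 0L else 1L, filt)
  }
  chan_tab <- do.call(rbind, lapply(specs, code))
  net_spec <- function(net) {
    list(kind = as.integer(net$units == "div"),
         W = net$W, b = net$b,
         mW = lapply(net$mask_W, function(m) matrix(as.integer(m), nrow = 2)),
         mb = lapply(net$mask_b, as.integer),
         Wout = net$Wout, bout = net$bout,
         mWout = as.integer(net$mask_out),
         mbout = as.integer(net$mask_bout),
         chan = match(net$channels, nms) - 1L)
  }
  list(chan_tab = chan_tab,
       filter_names = names(model$bank$filters),
       dscales = vapply(names(model$bank$filters), function(nm)
         model$grid$dx^sum(model$bank$filters[[nm]]$order), 0),
       trainable = vapply(model$bank$filters, function(f) f$trainable, TRUE),
       net_spec = net_spec)
}

# Compiled fast path for the 1-D teacher-forced construction.
loss_and_grad_cpp <- function(theta, model, ds, cfg, want_grad = TRUE) {
  model <- model_set_params(model, theta)
  n <- cfg$n_blocks
  stopifnot(n <= ds$K, ds$M > 0)
  w <- space_weight(model$grid)
  scale <- 1 / (n * ds$M * ds$dt^2)
  clip_c <- 5 * max(max(abs(ds$U)), max(abs(ds$V)), 1e-12)
  plan <- build_cpp_plan(model)
  bu <- stack_blocks(ds, n, "U"); bv <- stack_blocks(ds, n, "V")
  kern <- lapply(plan$filter_names, function(nm) bank_kernel(model$bank, nm))
  res <- .fp_loss1d_teacher(
    bu$start, bv$start, bu$target, bv$target,
    kern, plan$dscales, plan$trainable, plan$chan_tab,
    plan$net_spec(model$net1), plan$net_spec(model$net2),
    if (!is.null(model$eta)) model$eta else 0, !is.null(model$eta),
    cfg$n_substeps, ds$dt / cfg$n_substeps, scale, w,
    clip_c, 2 * clip_c, model$net1$eps_div, model$net1$pen_tau,
    cfg$pen_div, want_grad)
  if (isTRUE(res$blown)) {
    out <- list(total = 1e10, Ldata = 1e10, Lmoment = 0, LSymNet = 0,
                penalty = 0)
    if (want_grad) out$grad <- numeric(length(theta))
    return(out)
  }
  fm <- bank_free_moments(model$bank)
  wts <- c(symnet_get_params(model$net1), symnet_get_params(model$net2))
  Lmoment <- sum(huber(fm, cfg$s))
  LSymNet <- sum(huber(wts, cfg$s))
  out <- list(total = res$Ldata + cfg$lambda_M * Lmoment +
                cfg$lambda_S * LSymNet + cfg$pen_div * res$penalty,
              Ldata = res$Ldata, Lmoment = Lmoment, LSymNet = LSymNet,
              penalty = res$penalty)
  if (!want_grad) return(out)
  gbank <- numeric(0)
  for (i in seq_along(plan$filter_names)) {
    nm <- plan$filter_names[i]
    if (!model$bank$filters[[nm]]$trainable) next
    gbank <- c(gbank, kernel_grad_to_theta(model$bank, nm,
                                           drop(res$gq[[i]])))
  }
  gbank <- gbank + cfg$lambda_M * bank_moment_grad(model$bank,
                                                   huber_grad(fm, cfg$s))
  reshape_g <- function(net, g) {
    list(gW = lapply(g$W, function(x) matrix(x, nrow = 2)),
         gb = lapply(g$b, as.numeric),
         gWout = as.numeric(g$Wout), gbout = g$bout)
  }
  g1 <- symnet_flatten_grads(model$net1, reshape_g(model$net1, res$g1)) +
    cfg$lambda_S * huber_grad(symnet_get_params(model$net1), cfg$s)
  g2 <- symnet_flatten_grads(model$net2, reshape_g(model$net2, res$g2)) +
    cfg$lambda_S * huber_grad(symnet_get_params(model$net2), cfg$s)
  out$grad <- c(gbank, g1, g2, if (!is.null(model$eta)) res$geta)
  out
}

# Core objective: loss and (optionally) its exact gradient w.r.t. the flat
# parameter vector.  The backward pass checkpoints micro-step states and
# recomputes channel caches, keeping memory linear in the state size.
loss_and_grad <- function(theta, model, ds, cfg, want_grad = TRUE) {
  if (cfg$rollout == "teacher" && model$grid$dim == 1 &&
      isTRUE(getOption("fracpde.use_compiled", TRUE)))
    return(loss_and_grad_cpp(theta, model, ds, cfg, want_grad))
  model <- model_set_params(model, theta)
  kern <- bank_kernels(model$bank, model$grid$n)
  grid <- model$grid
  n <- cfg$n_blocks
  m <- cfg$n_substeps
  stopifnot(n <= ds$K, ds$M > 0)
  w <- space_weight(grid)
  scale <- 1 / (n * ds$M * ds$dt^2)
  delta <- ds$dt / m
  teacher <- cfg$rollout == "teacher"

  bad <- function() {
    out <- list(total = 1e10, Ldata = 1e10, Lmoment = 0, LSymNet = 0,
                penalty = 0)
    if (want_grad) out$grad <- numeric(length(theta))
    out
  }

  Ldata <- 0; penalty <- 0
  nstep_pen <- n * m
  clip_c <- 5 * max(max(abs(ds$U)), max(abs(ds$V)), 1e-12)
  clip_B <- 2 * clip_c
  if (teacher) {
    ## all blocks advanced together as one batch of n * M trajectories
    bu <- stack_blocks(ds, n, "U"); bv <- stack_blocks(ds, n, "V")
    u <- bu$start; v <- bv$start
    states <- vector("list", m)
    for (s in seq_len(m)) {
      states[[s]] <- list(u = u, v = v)
      r <- rhs_forward(model, kern, u, v)
      penalty <- penalty + r$penalty / nstep_pen
      u <- soft_clip(u + delta * r$F1, clip_c, clip_B)
      v <- soft_clip(v + delta * r$F2, clip_c, clip_B)
      if (!all(is.finite(u)) || !all(is.finite(v))) return(bad())
    }
    ru <- u - bu$target; rv <- v - bv$target
    Ldata <- scale * w * (sum(ru^2) + sum(rv^2))
  } else {
    ## one chained rollout; residuals at block boundaries
    u <- ds_block(ds, 0, "U"); v <- ds_block(ds, 0, "V")
    states <- vector("list", n * m)
    resid_u <- vector("list", n); resid_v <- vector("list", n)
    for (k in seq_len(n)) {
      for (s in seq_len(m)) {
        states[[(k - 1) * m + s]] <- list(u = u, v = v)
        r <- rhs_forward(model, kern, u, v)
        penalty <- penalty + r$penalty / nstep_pen
        u <- soft_clip(u + delta * r$F1, clip_c, clip_B)
        v <- soft_clip(v + delta * r$F2, clip_c, clip_B)
        if (!all(is.finite(u)) || !all(is.finite(v))) return(bad())
      }
      du <- u - ds_block(ds, k, "U")
      dv <- v - ds_block(ds, k, "V")
      resid_u[[k]] <- du; resid_v[[k]] <- dv
      Ldata <- Ldata + scale * w * (sum(du^2) + sum(dv^2))
    }
  }

  fm <- bank_free_moments(model$bank)
  wts <- c(symnet_get_params(model$net1), symnet_get_params(model$net2))
  Lmoment <- sum(huber(fm, cfg$s))
  LSymNet <- sum(huber(wts, cfg$s))
  total <- Ldata + cfg$lambda_M * Lmoment + cfg$lambda_S * LSymNet +
    cfg$pen_div * penalty
  out <- list(total = total, Ldata = Ldata, Lmoment = Lmoment,
              LSymNet = LSymNet, penalty = penalty)
  if (!want_grad) return(out)

  acc <- new.env()
  acc$gq <- lapply(kern$q, function(q) 0 * q)
  acc$g1 <- numeric(length(symnet_get_params(model$net1)))
  acc$g2 <- numeric(length(symnet_get_params(model$net2)))
  acc$geta <- 0
  pen_w <- cfg$pen_div / nstep_pen
  back_step <- function(st, au, av) {
    r <- rhs_forward(model, kern, st$u, st$v, want_cache = TRUE)
    zu <- st$u + delta * r$F1
    zv <- st$v + delta * r$F2
    au <- au * soft_clip_grad(zu, clip_c, clip_B)
    av <- av * soft_clip_grad(zv, clip_c, clip_B)
    bk <- rhs_backward(model, kern, r$cache, gF1 = delta * au,
                       gF2 = delta * av, acc, pen_w = pen_w)
    list(au = au + bk$gU, av = av + bk$gV)
  }
  if (teacher) {
    au <- 2 * scale * w * ru
    av <- 2 * scale * w * rv
    for (s in rev(seq_len(m))) {
      res <- back_step(states[[s]], au, av)
      au <- res$au; av <- res$av
    }
  } else {
    au <- 0 * u; av <- 0 * v
    for (k in rev(seq_len(n))) {
      au <- au + 2 * scale * w * resid_u[[k]]
      av <- av + 2 * scale * w * resid_v[[k]]
      for (s in rev(seq_len(m))) {
        res <- back_step(states[[(k - 1) * m + s]], au, av)
        au <- res$au; av <- res$av
      }
    }
  }
  gbank <- numeric(0)
  for (nm in names(model$bank$filters)) {
    f <- model$bank$filters[[nm]]
    if (!f$trainable) next
    gth <- kernel_grad_to_theta(model$bank, nm, acc$gq[[nm]])
    gbank <- c(gbank, gth)
  }
  gbank <- gbank + cfg$lambda_M * bank_moment_grad(model$bank,
                                                   huber_grad(fm, cfg$s))
  g1 <- acc$g1 + cfg$lambda_S *
    huber_grad(symnet_get_params(model$net1), cfg$s)
  g2 <- acc$g2 + cfg$lambda_S *
    huber_grad(symnet_get_params(model$net2), cfg$s)
  out$grad <- c(gbank, g1, g2, if (!is.null(model$eta)) acc$geta)
  out
}

## ---- optimization -------------------------------------------------------

# Box bounds over the flat parameter vector: the own-field diffusion
# read-out weights (uxx/uyy in the first equation, vxx/vyy in the second)
# are constrained nonnegative -- the model class assumes positive diffusion
# coefficients, and a negative one makes the rollout unconditionally
# unstable.  Everything else is unbounded.
model_param_bounds <- function(model) {
  net_bounds <- function(net, own) {
    lo <- rep(-Inf, length(symnet_get_params(net)))
    pos <- 0L
    for (i in seq_along(net$units))
      pos <- pos + sum(net$mask_W[[i]]) + sum(net$mask_b[[i]])
    outpos <- pos + cumsum(net$mask_out)  # flat index of each masked Wout
    diff_ch <- paste0(own, c("xx", "yy"))
    for (c in seq_along(net$channels)) {
      if (net$mask_out[c] && net$channels[c] %in% diff_ch)
        lo[outpos[c]] <- 0
    }
    lo
  }
  lo <- c(rep(-Inf, length(bank_get_theta(model$bank))),
          net_bounds(model$net1, "u"),
          net_bounds(model$net2, "v"),
          if (!is.null(model$eta)) -Inf)
  list(lower = lo, upper = rep(Inf, length(lo)))
}

unit_labels <- function(net) {
  if (length(net$units) == 0) character(0)
  else paste0("f", seq_along(net$units))
}

# Flat index of one read-out weight of one equation's network.
model_out_index <- function(model, eq, channel) {
  nb <- length(bank_get_theta(model$bank))
  off <- nb + if (eq == 2) length(symnet_get_params(model$net1)) else 0
  net <- if (eq == 1) model$net1 else model$net2
  pos <- 0L
  for (i in seq_along(net$units))
    pos <- pos + sum(net$mask_W[[i]]) + sum(net$mask_b[[i]])
  outpos <- pos + cumsum(net$mask_out)
  labels <- c(net$channels, unit_labels(net))
  c <- match(channel, labels)
  stopifnot(!is.na(c), net$mask_out[c])
  off + outpos[c]
}

# Profiled warm start for stiff identification (1-D teacher construction).
# For each equation, the nonlinear library channels and unit outputs are
# frozen at their block-start values (fields drift ~1% per block, so they
# act as quasi-static sources); the remaining block map is linear,
#   x_{s+1} = x_s + delta (w_d Lap x_s + w_lin x_s + sum_j c_j S_j),
# and for each (w_d, w_lin) on a grid the source coefficients c_j have a
# closed-form ridge solution.  The best grid point seeds the read-out
# layer; everything is then polished by the joint curriculum.  This removes
# the spurious "identity map" local minimum that gradient training falls
# into when a stiff diffusion coefficient must be grown from near zero.
# Structured unit initialization: every hidden unit starts as the plain
# product or ratio of its designated inputs (unit weight on the first
# allowed channel for eta, on the most recent allowed input for xi, biases
# zero), and each division denominator gets a bias at the typical magnitude
# of its inputs so it starts well clear of the safeguard.  The units then
# compute their architecturally intended quantities (v^2, u/(quad + c),
# u^alpha * I, ...) from the first iteration instead of random mixtures.
structured_unit_init <- function(net, chan) {
  nch <- length(net$channels)
  vals <- chan[net$channels]
  for (i in seq_along(net$units)) {
    W <- matrix(0, 2, nch + i - 1)
    b <- c(0, 0)
    allowed1 <- which(net$mask_W[[i]][1, ])
    allowed2 <- which(net$mask_W[[i]][2, ])
    pick1 <- allowed1[1]                    # first allowed input
    pick2 <- allowed2[length(allowed2)]     # most recent allowed input
    W[1, pick1] <- 1
    W[2, pick2] <- 1
    eta <- vals[[pick1]]
    xi <- vals[[pick2]]
    if (net$units[i] == "div" && net$mask_b[[i]][2]) {
      b[2] <- max(mean(abs(xi)), 1e-3)
      xi <- xi + b[2]
    }
    net$W[[i]] <- W
    net$b[[i]] <- b
    vals[[nch + i]] <- if (net$units[i] == "mul") eta * xi else eta / xi
  }
  net
}

# Random weights + structured units (no profiled read-out scan): the
# initialization used where the block map is not stiff.
structured_theta <- function(model, ds, seed) {
  theta <- model_init_params(model, seed)
  model <- model_set_params(model, theta)
  kern <- bank_kernels(model$bank, model$grid$n)
  u0 <- ds_block(ds, 0, "U"); v0 <- ds_block(ds, 0, "V")
  r0 <- rhs_forward(model, kern, u0, v0, want_cache = TRUE)
  model$net1 <- structured_unit_init(model$net1, r0$cache$chan)
  model$net2 <- structured_unit_init(model$net2, r0$cache$chan)
  model_get_params(model)
}

warm_start_theta <- function(model, ds, cfg, seed) {
  theta <- model_init_params(model, seed)
  if (model$grid$dim != 1) return(structured_theta(model, ds, seed))
  model <- model_set_params(model, theta)
  kern <- bank_kernels(model$bank, model$grid$n)
  n <- min(cfg$n_blocks, ds$K)
  m <- cfg$n_substeps
  delta <- ds$dt / m
  bu <- stack_blocks(ds, n, "U"); bv <- stack_blocks(ds, n, "V")
  pre <- rhs_forward(model, kern, bu$start, bv$start, want_cache = TRUE)
  model$net1 <- structured_unit_init(model$net1, pre$cache$chan)
  model$net2 <- structured_unit_init(model$net2, pre$cache$chan)
  theta <- model_get_params(model)
  r0 <- rhs_forward(model, kern, bu$start, bv$start, want_cache = TRUE)
  dmax <- stable_diffusion_limit(model$grid, ds$dt, m)
  lapm <- function(X) {
    nr <- nrow(X)
    (rbind(X[1, , drop = FALSE], X[-nr, , drop = FALSE]) - 2 * X +
       rbind(X[-1, , drop = FALSE], X[nr, , drop = FALSE])) / model$grid$dx^2
  }
  for (eq in 1:2) {
    net <- if (eq == 1) model$net1 else model$net2
    sn <- if (eq == 1) r0$cache$sn1 else r0$cache$sn2
    own <- if (eq == 1) "u" else "v"
    X0 <- if (eq == 1) bu$start else bv$start
    Tg <- if (eq == 1) bu$target else bv$target
    labels <- c(net$channels, unit_labels(net))
    keep <- which(net$mask_out &
                    !(labels %in% c(own, paste0(own, "xx"))))
    S <- lapply(keep, function(c) sn$L[[c]])
    if (net$mask_bout) S <- c(S, list(matrix(1, nrow(X0), ncol(X0))))
    best <- NULL
    for (wd in dmax * c(0.002, 0.01, 0.05, 0.15, 0.3, 0.5, 0.7, 0.85)) {
      for (wl in c(-6, -3, -1.5, -0.5, 0, 0.5)) {
        A <- function(X) X + delta * (wd * lapm(X) + wl * X)
        Xh <- X0
        G <- lapply(S, function(s) matrix(0, nrow(X0), ncol(X0)))
        for (s in seq_len(m)) {
          for (j in seq_along(S)) G[[j]] <- A(G[[j]]) + delta * S[[j]]
          Xh <- A(Xh)
        }
        R <- as.numeric(Tg - Xh)
        M <- vapply(G, as.numeric, numeric(length(R)))
        cf <- tryCatch(ridge_solve(M, R, 1e-8 * nrow(M)),
                       error = function(e) NULL)
        if (is.null(cf)) next
        rss <- sum((R - M %*% cf)^2)
        if (is.null(best) || rss < best$rss)
          best <- list(wd = wd, wl = wl, cf = cf, rss = rss)
      }
    }
    if (is.null(best)) next
    theta[model_out_index(model, eq, paste0(own, "xx"))] <- best$wd
    theta[model_out_index(model, eq, own)] <- best$wl
    for (j in seq_along(keep))
      theta[model_out_index(model, eq, labels[keep[j]])] <- best$cf[j]
    # bias handled through the trailing column when present
    if (net$mask_bout) {
      nb <- length(bank_get_theta(model$bank))
      off <- nb + if (eq == 2) length(symnet_get_params(model$net1)) else 0
      theta[off + length(symnet_get_params(net))] <-
        best$cf[length(best$cf)]
    }
  }
  theta
}

# Flat indices of the own-field second-derivative read-out weights (the
# diffusion coefficients d1, d2).
model_diffusion_indices <- function(model) {
  nb <- length(bank_get_theta(model$bank))
  idx <- integer(0)
  off <- nb
  for (eq in 1:2) {
    net <- if (eq == 1) model$net1 else model$net2
    own <- if (eq == 1) "u" else "v"
    pos <- 0L
    for (i in seq_along(net$units))
      pos <- pos + sum(net$mask_W[[i]]) + sum(net$mask_b[[i]])
    outpos <- pos + cumsum(net$mask_out)
    for (c in seq_along(net$channels)) {
      if (net$mask_out[c] && net$channels[c] %in% paste0(own, c("xx", "yy")))
        idx <- c(idx, off + outpos[c])
    }
    off <- off + length(symnet_get_params(net))
  }
  idx
}

# Largest diffusion coefficient whose explicit micro-step is stable for the
# compact second-derivative stencil (response 4/dx^2 in 1-D, 8/dx^2 in 2-D).
stable_diffusion_limit <- function(grid, dt, n_substeps) {
  lam <- 4 * grid$dim / grid$dx^2
  2 * n_substeps / (dt * lam)
}

#' Train a model with an expanding-window curriculum
#'
#' `Nt` stages: stage number r fits the rollout loss on the first `K r / Nt`
#' time blocks of the training trajectories, warm-starting from the
#' previous stage, each stage running L-BFGS to gradient tolerance `1e-8`
#' or the iteration cap.  Deterministic given `seed`.
#'
#' @param train_ds training `fp_dataset`.
#' @param cfg a [loss_config()] (its `n_blocks` is set per stage).
#' @param model an `fp_nnmodel` (from [fracpde_model()]).
#' @param K total number of blocks used (default `train_ds$K`).
#' @param Nt number of curriculum stages (must divide `K`).
#' @param seed integer seed for the weight initialization.
#' @param maxit iteration cap per stage (scalar or per-stage vector).
#' @param valid_ds optional validation dataset; per-stage validation losses
#'   are recorded.
#' @param theta0 optional explicit initial parameter vector.
#' @param warm_start use the profiled warm start (grid scan of the stiff
#'   linear pair with closed-form source coefficients) to seed the read-out
#'   layer; default on for the teacher-forced construction, where growing a
#'   stiff diffusion coefficient from near zero by gradient descent stalls
#'   in an "identity map" local minimum.  Hidden units are structurally
#'   initialized (plain products / ratios of their designated inputs)
#'   either way.
#' @return a `fp_trained` object: `model` (with final parameters),
#'   `history` (per-stage data frame), `cfg`.
#' @export
train <- function(train_ds, cfg, model, K = train_ds$K, Nt = 5, seed = 1,
                  maxit = 200, valid_ds = NULL, theta0 = NULL,
                  substeps = NULL,
                  warm_start = cfg$rollout == "teacher") {
  stopifnot(K %% Nt == 0, train_ds$M > 0)
  if (is.null(theta0)) {
    theta0 <- if (warm_start)
      warm_start_theta(model, train_ds, cfg, seed)
    else structured_theta(model, train_ds, seed)
  }
  if (length(maxit) == 1) maxit <- rep(maxit, Nt)
  if (is.null(substeps)) substeps <- rep(cfg$n_substeps, Nt)
  if (length(substeps) == 1) substeps <- rep(substeps, Nt)
  theta <- theta0
  bounds <- model_param_bounds(model)
  nb <- length(bank_get_theta(model$bank))
  netpar <- seq(nb + 1, length(theta0))   # network weights (+ eta)
  hist <- NULL
  for (r in seq_len(Nt)) {
    cfg_r <- cfg; cfg_r$n_blocks <- r * K / Nt
    cfg_r$n_substeps <- substeps[r]
    # a warm start carried into a finer block construction can sit outside
    # its stability region: damp the network weights until feasible
    for (try in 1:30) {
      if (loss_and_grad(theta, model, train_ds, cfg_r,
                        want_grad = FALSE)$total < 1e9) break
      theta[netpar] <- 0.7 * theta[netpar]
    }
    # fn/gr share one evaluation per parameter point
    memo <- new.env()
    evalpt <- function(th) {
      if (!is.null(memo$th) && identical(th, memo$th)) return(memo$res)
      memo$th <- th
      memo$res <- loss_and_grad(th, model, train_ds, cfg_r)
      memo$res
    }
    fn <- function(th) evalpt(th)$total
    gr <- function(th) evalpt(th)$grad
    # L-BFGS restarts (fresh curvature memory) until the stage budget is
    # spent: on this loss the line search can stall in narrow, badly
    # conditioned valleys, and a restart usually resumes progress.
    budget <- maxit[r]
    opt <- NULL
    while (budget > 0) {
      o <- stats::optim(if (is.null(opt)) theta else opt$par, fn, gr,
                        method = "L-BFGS-B",
                        lower = bounds$lower, upper = bounds$upper,
                        control = list(maxit = budget, pgtol = 0,
                                       factr = 1e2))
      used <- max(o$counts[1], 5)
      budget <- budget - used
      improved <- is.null(opt) || o$value < opt$value - 1e-14
      if (is.null(opt) || o$value <= opt$value) opt <- o
      if (o$convergence == 0 || !improved) break
    }
    theta <- opt$par
    comp <- loss_and_grad(theta, model, train_ds, cfg_r, want_grad = FALSE)
    vl <- NA_real_
    if (!is.null(valid_ds) && valid_ds$M > 0) {
      m2 <- model_set_params(model, theta)
      vl <- validation_loss(m2, valid_ds, cfg_r$n_blocks, cfg_r)
    }
    hist <- rbind(hist, data.frame(
      stage = r, blocks = cfg_r$n_blocks, iterations = opt$counts[1],
      convergence = opt$convergence,
      total = comp$total, Ldata = comp$Ldata, Lmoment = comp$Lmoment,
      LSymNet = comp$LSymNet, valid = vl))
  }
  structure(list(model = model_set_params(model, theta), history = hist,
                 cfg = cfg, seed = seed),
            class = "fp_trained")
}

#' @export
print.fp_trained <- function(x, ...) {
  cat("<fp_trained>\n")
  print(x$history, row.names = FALSE)
  invisible(x)
}

# Pure data-misfit validation loss over the first `n` blocks (no
# regularization): 1/(M K dt^2) sum ||obs - pred||_2^2 over both fields,
# with the same block construction as the training loss.
validation_loss <- function(model, ds, n = ds$K, cfg = NULL) {
  vcfg <- loss_config(n_blocks = n,
                      rollout = if (is.null(cfg)) "multi" else cfg$rollout,
                      n_substeps = if (is.null(cfg)) 1 else cfg$n_substeps)
  lg <- loss_and_grad(model_get_params(model), model, ds, vcfg,
                      want_grad = FALSE)
  lg$Ldata
}
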