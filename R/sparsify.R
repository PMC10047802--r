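## Sparsification of a trained symbolic expression: identifiability-driven
## term merging, L2-norm term selection, sequential-threshold ridge
## regression (STRidge), and coefficient retraining under the rollout loss.

#' Merge near-degenerate rational terms into their polynomial main part
#'
#' Every rational term whose numerator degree (in the denominator variable)
#' reaches the denominator degree is polynomial-divided, e.g.
#' `u^2/(u + e) = u - e + e^2/(u + e)` and `u v/(v + e) = u - u e/(v + e)`;
#' the quotient is merged into the matching monomial terms.  Any term --
#' leftover proper fraction or quotient crumb -- whose sup-norm over the
#' observed data range is below `eps_merge` is dropped, and identical
#' monomials are collected.
#'
#' @param expr an `fp_expression`.
#' @param eps_merge absolute sup-norm threshold; when `NULL`, 1% of the
#'   sup-norm of the largest retained polynomial term.
#' @param ranges named list of ranges for the base fields, e.g.
#'   `list(u = c(0.5, 2), v = c(0, 1))`, defining the data region on which
#'   sup-norms are measured.
#' @return the merged `fp_expression`.
#' @export
merge_terms <- function(expr, eps_merge = NULL, ranges) {
  grid_env <- range_grid(ranges, expr$alpha)
  deriv_syms <- c("ux", "uxx", "uyy", "vx", "vxx", "vyy")
  mono <- list()   # key -> term
  frac <- list()
  protected <- list()   # derivative terms are never merge candidates
  add_mono <- function(coef, pow) {
    key <- mono_key(pow)
    if (is.null(mono[[key]])) mono[[key]] <<- fp_term(coef, pow)
    else mono[[key]]$coef <<- mono[[key]]$coef + coef
  }
  for (tm in expr$terms) {
    if (any(names(tm$pow) %in% deriv_syms)) {
      protected[[length(protected) + 1]] <- tm
      next
    }
    if (is.null(tm$ratio)) { add_mono(tm$coef, tm$pow); next }
    var <- tm$ratio$var
    num <- poly_scale(tm$ratio$num, tm$coef)
    den <- tm$ratio$den
    if (poly_is_zero(den)) stop("rational term with zero denominator")
    if (!is.na(var) && poly_deg(num, var) >= poly_deg(den, var)) {
      dm <- poly_divmod(num, den, var)
      for (mn in dm$quotient) add_mono(mn$coef, mn$pow)
      num <- dm$remainder
    }
    if (!poly_is_zero(num))
      frac[[length(frac) + 1]] <- fp_term(1, tm$pow,
                                          list(num = num, den = den,
                                               var = var))
  }
  sup <- function(tm) {
    v <- tryCatch(term_eval_with_coef(tm, grid_env),
                  error = function(e) NA_real_)
    if (length(v) == 0 || any(is.na(v))) return(NA_real_)
    max(abs(v))
  }
  if (is.null(eps_merge)) {
    sups <- vapply(mono, sup, 0)
    sups <- sups[is.finite(sups)]
    eps_merge <- if (length(sups)) 0.01 * max(sups) else 0.01
  }
  keep <- function(tm) {
    s <- sup(tm)
    is.finite(s) && s >= eps_merge
  }
  out <- c(protected, Filter(keep, mono), Filter(keep, frac))
  # renormalize surviving fractions back to coef * (num/den) form
  out <- lapply(out, function(tm) {
    if (is.null(tm$ratio)) return(tm)
    nr <- normalize_ratio(poly_scale(tm$ratio$num, tm$coef), tm$ratio$den)
    nr$pow <- tm$pow
    nr
  })
  structure(list(terms = unname(out), alpha = expr$alpha),
            class = "fp_expression")
}

# Evaluation grid spanning the data ranges (for sup-norm decisions).
range_grid <- function(ranges, alpha = NA_real_, n = 21) {
  vars <- names(ranges)
  grids <- lapply(ranges, function(r) seq(r[1], r[2], length.out = n))
  env <- if (length(vars) == 1) {
    stats::setNames(list(grids[[1]]), vars)
  } else {
    eg <- expand.grid(grids)
    stats::setNames(lapply(seq_along(vars), function(i) eg[[i]]), vars)
  }
  if (!is.null(env$u) && !is.na(alpha)) env$ua <- pmax(env$u, 0)^alpha
  env
}

## ---- design matrix -------------------------------------------------------

# Library channel values of an observed dataset, evaluated with exact
# finite-difference stencils (mirror boundary), as one long sample vector
# per channel.  Uses blocks 0..K-1 (forward differences define the target).
dataset_env <- function(ds, alpha = NA_real_) {
  g <- ds$grid
  n <- g$n
  env <- list()
  blocks <- seq_len(ds$K) - 1L
  pull <- function(what) lapply(blocks, function(k) ds_block(ds, k, what))
  Us <- pull("U"); Vs <- pull("V")
  if (g$dim == 1) {
    d1 <- function(M) (rbind(M[-1, , drop = FALSE], M[n, , drop = FALSE]) -
                       rbind(M[1, , drop = FALSE], M[-n, , drop = FALSE])) /
      (2 * g$dx)
    env$u  <- unlist(Us); env$v <- unlist(Vs)
    env$ux <- unlist(lapply(Us, d1)); env$vx <- unlist(lapply(Vs, d1))
    env$uxx <- unlist(lapply(Us, function(M)
      apply(M, 2, lap1d, dx = g$dx)))
    env$vxx <- unlist(lapply(Vs, function(M)
      apply(M, 2, lap1d, dx = g$dx)))
    env$I <- unlist(lapply(Us, function(M)
      matrix(g$dx * colSums(M), n, ncol(M), byrow = TRUE)))
  } else {
    env$u <- unlist(Us); env$v <- unlist(Vs)
    lap_stack <- function(As) unlist(lapply(As, function(A) {
      out <- A
      for (j in seq_len(dim(A)[3])) out[, , j] <- lap2d(A[, , j], g$dx)
      out
    }))
    # separate x / y second differences
    dxx <- function(A) {
      up <- rbind(A[1, , drop = FALSE], A[-n, , drop = FALSE])
      dn <- rbind(A[-1, , drop = FALSE], A[n, , drop = FALSE])
      (up + dn - 2 * A) / g$dx^2
    }
    sl <- function(As, f) unlist(lapply(As, function(A) {
      out <- A
      for (j in seq_len(dim(A)[3])) out[, , j] <- f(A[, , j])
      out
    }))
    env$uxx <- sl(Us, dxx); env$vxx <- sl(Vs, dxx)
    env$uyy <- sl(Us, function(M) t(dxx(t(M))))
    env$vyy <- sl(Vs, function(M) t(dxx(t(M))))
  }
  if (!is.na(alpha)) env$ua <- pmax(env$u, 0)^alpha
  env$.target_u <- as.numeric(unlist(lapply(seq_len(ds$K), function(k)
    (ds_block(ds, k, "U") - ds_block(ds, k - 1, "U")) / ds$dt)))
  env$.target_v <- as.numeric(unlist(lapply(seq_len(ds$K), function(k)
    (ds_block(ds, k, "V") - ds_block(ds, k - 1, "V")) / ds$dt)))
  env
}

#' Design matrix of candidate terms against time-derivative targets
#'
#' Evaluates every term of the expression (without its coefficient) on all
#' retained samples (space x block x trajectory) of the observed dataset;
#' the target is the forward time difference of the observed snapshots.
#' Rational terms are evaluated with their trained denominator coefficients
#' frozen.  Non-finite or all-zero columns are dropped with a warning.
#'
#' @param expr an `fp_expression`.
#' @param ds an `fp_dataset`.
#' @param target `"u"` or `"v"`: which field's time derivative to target.
#' @param target_source `"forward_diff"`: forward time differences of the
#'   observed snapshots; `"model_rhs"`: the trained expression evaluated on
#'   the observed snapshots (a projection target).  The forward-difference
#'   estimate is biased whenever fast modes relax within one observation
#'   step (the stiff 1-D benchmark), where the projection form is the
#'   right choice; the final coefficients come from rollout retraining
#'   either way.
#' @return list of class `fp_design`: `Theta` (samples x terms), `Ut`,
#'   `terms`, `labels`, `grid`.
#' @export
build_design_matrix <- function(expr, ds, target = "u",
                                target_source = c("forward_diff",
                                                  "model_rhs")) {
  target_source <- match.arg(target_source)
  stopifnot(length(expr$terms) > 0)
  env <- dataset_env(ds, expr$alpha)
  cols <- lapply(expr$terms, function(tm) as.numeric(term_eval(tm, env)))
  labels <- vapply(expr$terms, term_label, "")
  ok <- vapply(cols, function(x) all(is.finite(x)) && any(x != 0), TRUE)
  if (!all(ok))
    warning("dropping degenerate design columns: ",
            paste(labels[!ok], collapse = ", "))
  Theta <- do.call(cbind, cols[ok])
  colnames(Theta) <- labels[ok]
  qrT <- qr(Theta)
  if (qrT$rank < ncol(Theta))
    warning("design matrix is rank deficient (duplicate or collinear terms)")
  Ut <- if (target_source == "model_rhs")
    as.numeric(expression_eval(expr, env))
  else if (target == "u") env$.target_u else env$.target_v
  structure(list(Theta = Theta, Ut = Ut,
                 terms = expr$terms[ok], labels = labels[ok],
                 grid = ds$grid, alpha = expr$alpha),
            class = "fp_design")
}

## ---- selection and sparse regression ------------------------------------

#' L2-norm term selection
#'
#' Rescales each design column to unit discrete-L2 norm so coefficients
#' become comparable (`eta_k = xi_k * ||Theta_k||_2`), then zeroes every
#' coefficient with `|eta_k| < delta * max_j |eta_j|` and returns the
#' reduced system.
#'
#' @param dm an `fp_design` from [build_design_matrix()].
#' @param xi numeric coefficients attached to the columns (from the trained
#'   expression).
#' @param delta relative threshold in `(0, 1)`.
#' @return list of class `fp_selection`: `eta`, `keep` (logical),
#'   `Theta_s`, `terms`, `labels`, `xi_s`.
#' @export
l2_select <- function(dm, xi, delta) {
  stopifnot(delta > 0, delta < 1, length(xi) == ncol(dm$Theta))
  w <- sqrt(space_weight(dm$grid))
  norms <- w * sqrt(colSums(dm$Theta^2))
  eta <- xi * norms
  keep <- abs(eta) >= delta * max(abs(eta))
  if (!any(keep)) stop("l2_select removed every term; decrease delta")
  structure(list(eta = eta, keep = keep,
                 Theta_s = dm$Theta[, keep, drop = FALSE],
                 terms = dm$terms[keep], labels = dm$labels[keep],
                 xi_s = xi[keep], Ut = dm$Ut),
            class = "fp_selection")
}

#' Sequential-threshold ridge regression
#'
#' Ridge solution `argmin ||Theta xi - Ut||^2 + lambda ||xi||^2`, hard
#' thresholding of entries below `tol`, and recursion on the surviving
#' columns until the support stabilizes or `iters` is exhausted.  Zeroed
#' entries stay zero.
#'
#' @param Theta design matrix.
#' @param Ut target vector.
#' @param lambda ridge penalty (`>= 0`).
#' @param tol hard threshold on coefficient magnitude.
#' @param iters maximum recursion depth.
#' @return coefficient vector over the original columns.
#' @export
stridge <- function(Theta, Ut, lambda, tol, iters = 10) {
  stopifnot(iters >= 0, lambda >= 0)
  p <- ncol(Theta)
  xi <- ridge_solve(Theta, Ut, lambda)
  big <- abs(xi) >= tol
  if (!any(big)) {
    warning("stridge: every coefficient fell below tol; returning zeros")
    return(numeric(p))
  }
  if (all(big) || iters == 0) {
    xi[!big] <- 0
    return(xi)
  }
  out <- numeric(p)
  out[big] <- stridge(Theta[, big, drop = FALSE], Ut, lambda, tol, iters - 1)
  out
}

ridge_solve <- function(Theta, Ut, lambda) {
  A <- crossprod(Theta)
  diag(A) <- diag(A) + lambda
  drop(solve(A, crossprod(Theta, Ut)))
}

#' Sparsify a trained expression (term selection + STRidge)
#'
#' The full sparsification tail for one equation: [merge_terms()] for
#' identifiability, [build_design_matrix()], [l2_select()] with the trained
#' coefficients, then [stridge()] on the reduced system.
#'
#' @param expr trained `fp_expression` for the equation.
#' @param ds observed `fp_dataset`.
#' @param target `"u"` or `"v"`.
#' @param delta L2-selection threshold (default 0.05).
#' @param lambda ridge penalty (default 1e-5).
#' @param tol STRidge hard threshold (default 0.05).
#' @param iters STRidge recursion cap.
#' @param eps_merge see [merge_terms()].
#' @param target_source see [build_design_matrix()].
#' @return an `fp_expression` with the surviving terms and their STRidge
#'   coefficients.
#' @export
sparsify_model <- function(expr, ds, target = "u", delta = 0.05,
                           lambda = 1e-5, tol = 0.05, iters = 10,
                           eps_merge = NULL,
                           target_source = "forward_diff") {
  ranges <- list(u = range(ds$U), v = range(ds$V))
  if (ds$grid$dim == 1) {
    Ivals <- apply(ds$U, c(2, 3), function(col) ds$grid$dx * sum(col))
    ranges$I <- range(Ivals)
  }
  merged <- merge_terms(expr, eps_merge, ranges)
  dm <- build_design_matrix(merged, ds, target, target_source)
  xi0 <- vapply(dm$terms, function(tm) tm$coef, 0)
  sel <- l2_select(dm, xi0, delta)
  xi <- stridge(sel$Theta_s, sel$Ut, lambda, tol, iters)
  keep <- xi != 0
  terms <- sel$terms[keep]
  for (i in seq_along(terms)) terms[[i]]$coef <- xi[keep][i]
  structure(list(terms = terms, alpha = merged$alpha),
            class = "fp_expression")
}

## ---- coefficient retraining ----------------------------------------------

# Flatten the free parameters of a sparse structure: term coefficients,
# denominator coefficients of rational terms, and the exponent (through
# eta) when a ua factor is present.
structure_get_params <- function(F1, F2) {
  th <- c(vapply(F1$terms, function(tm) tm$coef, 0),
          vapply(F2$terms, function(tm) tm$coef, 0))
  for (tm in c(F1$terms, F2$terms)) {
    if (!is.null(tm$ratio))
      th <- c(th, vapply(tm$ratio$den, function(m) m$coef, 0))
  }
  uses_alpha <- uses_ua(F1) || uses_ua(F2)
  if (uses_alpha) th <- c(th, asin(pmin(pmax((F1$alpha - 1.5) / 0.5, -1), 1)))
  th
}

structure_set_params <- function(F1, F2, th) {
  n1 <- length(F1$terms); n2 <- length(F2$terms)
  for (i in seq_len(n1)) F1$terms[[i]]$coef <- th[i]
  for (i in seq_len(n2)) F2$terms[[i]]$coef <- th[n1 + i]
  pos <- n1 + n2
  fill_den <- function(Fx) {
    for (i in seq_along(Fx$terms)) {
      tm <- Fx$terms[[i]]
      if (!is.null(tm$ratio)) {
        for (k in seq_along(tm$ratio$den)) {
          pos <<- pos + 1L
          Fx$terms[[i]]$ratio$den[[k]]$coef <- th[pos]
        }
      }
    }
    Fx
  }
  F1 <- fill_den(F1); F2 <- fill_den(F2)
  if (uses_ua(F1) || uses_ua(F2)) {
    pos <- pos + 1L
    al <- alpha_from_eta(th[pos])
    F1$alpha <- al; F2$alpha <- al
  }
  stopifnot(pos == length(th))
  list(F1 = F1, F2 = F2)
}

uses_ua <- function(Fx) {
  any(vapply(Fx$terms, function(tm) {
    "ua" %in% names(tm$pow) ||
      (!is.null(tm$ratio) && "ua" %in% poly_vars(tm$ratio$num))
  }, TRUE))
}

#' Retrain the coefficients of a fixed sparse structure
#'
#' Re-optimizes only the numeric content of the retained terms -- the term
#' coefficients, the denominator polynomial coefficients of retained
#' rational terms, and the exponent `alpha` where a fractional-power factor
#' was retained -- under the same rollout data loss as network training,
#' with the structure frozen.
#'
#' @param F1,F2 `fp_expression` structures for the two equations.
#' @param ds training `fp_dataset`.
#' @param cfg a [loss_config()] (its rollout mode, substeps and block count
#'   are used; regularization is not applied to the few retained
#'   coefficients).
#' @param maxit optimizer iteration cap.
#' @return `list(F1, F2, value)` with updated coefficients.
#' @export
retrain_coefficients <- function(F1, F2, ds, cfg, maxit = 200) {
  th0 <- structure_get_params(F1, F2)
  fn <- function(th) {
    st <- structure_set_params(F1, F2, th)
    sparse_data_loss(st$F1, st$F2, ds, cfg)
  }
  opt <- stats::optim(th0, fn, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e5),
                      lower = th0 - Inf, upper = th0 + Inf)
  st <- structure_set_params(F1, F2, opt$par)
  if (opt$value > fn(th0) + 1e-12) st <- structure_set_params(F1, F2, th0)
  list(F1 = st$F1, F2 = st$F2, value = min(opt$value, fn(th0)))
}

# Data loss of a term-based model under the block construction of `cfg`,
# using exact finite-difference stencils for the derivative channels.
sparse_data_loss <- function(F1, F2, ds, cfg) {
  g <- ds$grid
  n <- min(cfg$n_blocks, ds$K)
  m <- cfg$n_substeps
  delta <- ds$dt / m
  w <- space_weight(g)
  scale <- 1 / (n * ds$M * ds$dt^2)
  teacher <- cfg$rollout == "teacher"
  clip_c <- 5 * max(max(abs(ds$U)), max(abs(ds$V)), 1e-12)
  clip_B <- 2 * clip_c
  L <- 0
  if (teacher) {
    bu <- stack_blocks(ds, n, "U"); bv <- stack_blocks(ds, n, "V")
    u <- bu$start; v <- bv$start
    for (s in seq_len(m)) {
      r <- sparse_rhs(F1, F2, u, v, g)
      u <- soft_clip(u + delta * r$f1, clip_c, clip_B)
      v <- soft_clip(v + delta * r$f2, clip_c, clip_B)
      if (!all(is.finite(u)) || !all(is.finite(v))) return(1e10)
    }
    L <- scale * w * (sum((u - bu$target)^2) + sum((v - bv$target)^2))
  } else {
    u <- ds_block(ds, 0, "U"); v <- ds_block(ds, 0, "V")
    for (k in seq_len(n)) {
      for (s in seq_len(m)) {
        r <- sparse_rhs(F1, F2, u, v, g)
        u <- soft_clip(u + delta * r$f1, clip_c, clip_B)
        v <- soft_clip(v + delta * r$f2, clip_c, clip_B)
        if (!all(is.finite(u)) || !all(is.finite(v))) return(1e10)
      }
      L <- L + scale * w * (sum((u - ds_block(ds, k, "U"))^2) +
                              sum((v - ds_block(ds, k, "V"))^2))
    }
  }
  L
}

# Right-hand sides of a term-based model on batched state arrays, with
# exact stencils for derivative channels.
sparse_rhs <- function(F1, F2, u, v, g) {
  env <- state_env(u, v, g, F1$alpha)
  list(f1 = expression_eval(F1, env), f2 = expression_eval(F2, env))
}

state_env <- function(u, v, g, alpha = NA_real_) {
  n <- g$n
  env <- list(u = u, v = v)
  if (g$dim == 1) {
    u <- if (is.matrix(u)) u else matrix(u, ncol = 1)
    v <- if (is.matrix(v)) v else matrix(v, ncol = 1)
    lapm <- function(X) {
      up <- rbind(X[1, , drop = FALSE], X[-n, , drop = FALSE])
      dn <- rbind(X[-1, , drop = FALSE], X[n, , drop = FALSE])
      (up + dn - 2 * X) / g$dx^2
    }
    env$ux <- (rbind(u[-1, , drop = FALSE], u[n, , drop = FALSE]) -
               rbind(u[1, , drop = FALSE], u[-n, , drop = FALSE])) / (2 * g$dx)
    env$vx <- (rbind(v[-1, , drop = FALSE], v[n, , drop = FALSE]) -
               rbind(v[1, , drop = FALSE], v[-n, , drop = FALSE])) / (2 * g$dx)
    env$uxx <- lapm(u)
    env$vxx <- lapm(v)
    env$I <- matrix(g$dx * colSums(u), n, ncol(u), byrow = TRUE)
    if (!is.matrix(env$u)) {
      env$ux <- drop(env$ux); env$vx <- drop(env$vx)
      env$uxx <- drop(env$uxx); env$vxx <- drop(env$vxx)
      env$I <- drop(env$I)
    }
  } else {
    lap_batch <- function(A) {
      if (length(dim(A)) == 3) {
        out <- A
        for (j in seq_len(dim(A)[3])) out[, , j] <- lap2d(A[, , j], g$dx)
        out
      } else lap2d(A, g$dx)
    }
    dxx_one <- function(M) {
      up <- rbind(M[1, , drop = FALSE], M[-n, , drop = FALSE])
      dn <- rbind(M[-1, , drop = FALSE], M[n, , drop = FALSE])
      (up + dn - 2 * M) / g$dx^2
    }
    app <- function(A, f) {
      if (length(dim(A)) == 3) {
        out <- A
        for (j in seq_len(dim(A)[3])) out[, , j] <- f(A[, , j])
        out
      } else f(A)
    }
    env$uxx <- app(u, dxx_one); env$vxx <- app(v, dxx_one)
    env$uyy <- app(u, function(M) t(dxx_one(t(M))))
    env$vyy <- app(v, function(M) t(dxx_one(t(M))))
  }
  if (!is.na(alpha) && !is.null(alpha)) env$ua <- pmax(env$u, 0)^alpha
  env
}
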