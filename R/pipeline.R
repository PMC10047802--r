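## End-to-end orchestration: train -> expand -> sparsify -> retrain ->
## post-hoc compare -> predict, plus the error metrics of the prediction
## study.

#' Simulate a discovered (term-based) model forward
#'
#' Forward-Euler integration of the discovered right-hand side with exact
#' finite-difference stencils for the derivative channels (mirror-padded,
#' Neumann-consistent).  The internal step is sub-divided below the
#' diffusion stability limit; snapshots are reported at the requested
#' times.
#'
#' @param model `list(F1, F2)` of `fp_expression` structures.
#' @param u0,v0 initial fields.
#' @param grid an [fp_grid()].
#' @param times numeric vector of report times (first entry 0 reports the
#'   initial state).
#' @param dt_sim internal step; defaults to `0.8 * dx^2 / (2 d dim)` using
#'   the model's largest diffusion coefficient.
#' @return `list(U, V, times, ok)`: per-time snapshot lists; `ok = FALSE`
#'   if the state blew up (trajectory truncated).
#' @export
predict_sparse <- function(model, u0, v0, grid, times, dt_sim = NULL) {
  stopifnot(times[1] == 0, !is.unsorted(times))
  F1 <- model$F1; F2 <- model$F2
  if (is.null(dt_sim)) {
    dmax <- max(0.05, diffusion_coefs(F1, F2))
    dt_sim <- 0.8 * grid$dx^2 / (4 * grid$dim * dmax)
  }
  U <- vector("list", length(times)); V <- vector("list", length(times))
  U[[1]] <- u0; V[[1]] <- v0
  u <- u0; v <- v0
  tnow <- 0
  for (j in 2:length(times)) {
    nstep <- ceiling((times[j] - tnow) / dt_sim - 1e-9)
    h <- (times[j] - tnow) / nstep
    for (s in seq_len(nstep)) {
      r <- sparse_rhs(F1, F2, u, v, grid)
      u <- u + h * r$f1
      v <- v + h * r$f2
      if (!all(is.finite(u)) || !all(is.finite(v)) ||
          max(abs(u)) > 1e10 || max(abs(v)) > 1e10)
        return(list(U = U[seq_len(j - 1)], V = V[seq_len(j - 1)],
                    times = times[seq_len(j - 1)], ok = FALSE))
    }
    tnow <- times[j]
    U[[j]] <- u; V[[j]] <- v
  }
  list(U = U, V = V, times = times, ok = TRUE)
}

diffusion_coefs <- function(F1, F2) {
  out <- 0
  for (tm in c(F1$terms, F2$terms))
    if (is_diffusion_term(tm)) out <- max(out, abs(tm$coef))
  out
}

#' Prediction error norms
#'
#' `Linf` is the maximum absolute error; `L2` the discrete L2 norm with
#' grid-spacing weight.  With `per_time = TRUE` (the 2-D study convention)
#' errors are reported per evaluation time over the spatial domain; with
#' `per_time = FALSE` (the 1-D convention) a single pair of norms over the
#' whole space-time region (including the time weight `dt`) is returned.
#'
#' @param pred,truth trajectory lists as from [predict_sparse()]
#'   (matching times).
#' @param grid an [fp_grid()].
#' @param times indices (into the snapshot list) to evaluate.
#' @param per_time report per time (2-D convention) or pooled over
#'   space-time (1-D convention).
#' @return data frame with columns `time`, `field`, `linf`, `l2`.
#' @export
error_norms <- function(pred, truth, grid, times = NULL, per_time = TRUE) {
  nt <- min(length(pred$U), length(truth$U))
  if (is.null(times)) times <- seq_len(nt)[-1]
  w <- space_weight(grid)
  if (per_time) {
    out <- NULL
    for (k in times) {
      for (f in c("u", "v")) {
        e <- if (f == "u") pred$U[[k]] - truth$U[[k]] else
          pred$V[[k]] - truth$V[[k]]
        out <- rbind(out, data.frame(time = pred$times[k], field = f,
                                     linf = max(abs(e)),
                                     l2 = sqrt(w * sum(e^2))))
      }
    }
    out
  } else {
    dtv <- diff(pred$times[times[1:2]])
    acc <- c(u = 0, v = 0); mx <- c(u = 0, v = 0)
    for (k in times) {
      eu <- pred$U[[k]] - truth$U[[k]]
      ev <- pred$V[[k]] - truth$V[[k]]
      acc["u"] <- acc["u"] + w * dtv * sum(eu^2)
      acc["v"] <- acc["v"] + w * dtv * sum(ev^2)
      mx["u"] <- max(mx["u"], max(abs(eu)))
      mx["v"] <- max(mx["v"], max(abs(ev)))
    }
    data.frame(time = NA_real_, field = c("u", "v"),
               linf = as.numeric(mx), l2 = sqrt(as.numeric(acc)))
  }
}

#' Default experiment configuration for a benchmark
#'
#' Bundles the study settings: grid/time layout, noise level, tuned
#' regularization weights, sparsification thresholds and the training
#' schedule.  The defaults reproduce the benchmark conditions; every entry
#' can be overridden (e.g. smaller grids or fewer trajectories for
#' desk-scale runs).
#'
#' @param example 1 or 2.
#' @param nl noise level.
#' @param ... overrides of the defaults.
#' @return a list of class `fp_experiment_cfg`.
#' @export
experiment_config <- function(example, nl = if (example == 1) 0.05 else 0.01,
                              ...) {
  base <- if (example == 1) {
    list(example = 1, nl = nl, NInit = 12, n_grid = 64, NTime = 15,
         sizes = c(8, 2, 2), kmax = 3,
         lambda_M = 3.28e-5, lambda_S = 4.93e-5,
         rollout = "multi", substeps = 1, Nt = 5,
         maxit = c(60, 60, 60, 60, 150),
         delta = 0.05, ridge_lambda = 1e-5, tol = 0.05, iters = 10,
         retrain_maxit = 150, baseline = FALSE)
  } else {
    list(example = 2, nl = nl, NInit = 14, n_grid = 200, NTime = 15,
         sizes = c(10, 2, 2), kmax = 3,
         lambda_M = 1.88e-7, lambda_S = 1.62e-6,
         rollout = "teacher", substeps = 250, Nt = 5,
         maxit = c(60, 40, 40, 60, 250),
         delta = 0.05, ridge_lambda = 1e-5, tol = 0.05, iters = 10,
         retrain_maxit = 150, baseline = FALSE)
  }
  over <- list(...)
  base[names(over)] <- over
  structure(base, class = "fp_experiment_cfg")
}

#' Run a full discovery experiment
#'
#' The complete pipeline on synthetic data: generate -> train the network
#' model -> expand to a symbolic expression -> sparsify (L2 selection +
#' STRidge) -> retrain coefficients -> optionally post-hoc compare against
#' the drop-one model, and report everything needed for replay.
#'
#' @param cfg an [experiment_config()].
#' @param seed integer master seed.
#' @param posthoc also fit and test the drop-one model.
#' @param n_starts number of weight-initialization restarts of the network
#'   training; the fit with the lowest final validation loss (training
#'   loss when no validation set exists) continues through the pipeline.
#' @return a list bundle: `trained`, `expr` (raw expansions), `sparse`
#'   (selected structure), `final` (retrained model), `posthoc`
#'   (when requested), `data`, `cfg`, `seed`.
#' @export
run_example <- function(cfg, seed = 1, posthoc = FALSE, n_starts = 1) {
  d <- generate_example_data(cfg$example, nl = cfg$nl, seed = seed,
                             NInit = cfg$NInit, n_grid = cfg$n_grid,
                             NTime = cfg$NTime, sizes = cfg$sizes,
                             kmax = cfg$kmax)
  model <- fracpde_model(cfg$example, d$grid, dt = d$train$dt,
                         baseline = cfg$baseline)
  lcfg <- loss_config(lambda_M = cfg$lambda_M, lambda_S = cfg$lambda_S,
                      n_blocks = cfg$NTime, rollout = cfg$rollout,
                      n_substeps = max(cfg$substeps))
  trained <- NULL
  for (k in seq_len(n_starts)) {
    tr_k <- train(d$train, lcfg, model, K = cfg$NTime, Nt = cfg$Nt,
                  seed = seed + 1000L * (k - 1L), maxit = cfg$maxit,
                  substeps = cfg$substeps, valid_ds = d$valid)
    score <- function(tr) {
      last <- tr$history[nrow(tr$history), ]
      if (is.finite(last$valid)) last$valid else last$total
    }
    if (is.null(trained) || score(tr_k) < score(trained)) trained <- tr_k
  }
  mod <- trained$model
  alpha <- if (!is.null(mod$eta)) alpha_from_eta(mod$eta) else NA_real_
  expr1 <- symnet_to_expression(mod$net1, prune_tol = 1e-4, alpha = alpha)
  expr2 <- symnet_to_expression(mod$net2, prune_tol = 1e-4, alpha = alpha)
  tsrc <- if (cfg$rollout == "teacher") "model_rhs" else "forward_diff"
  s1 <- sparsify_model(expr1, d$train, target = "u", delta = cfg$delta,
                       lambda = cfg$ridge_lambda, tol = cfg$tol,
                       iters = cfg$iters, target_source = tsrc)
  s2 <- sparsify_model(expr2, d$train, target = "v", delta = cfg$delta,
                       lambda = cfg$ridge_lambda, tol = cfg$tol,
                       iters = cfg$iters, target_source = tsrc)
  rcfg <- loss_config(n_blocks = cfg$NTime, rollout = cfg$rollout,
                      n_substeps = max(cfg$substeps))
  final <- retrain_coefficients(s1, s2, d$train, rcfg,
                                maxit = cfg$retrain_maxit)
  out <- list(trained = trained, expr = list(F1 = expr1, F2 = expr2),
              sparse = list(F1 = s1, F2 = s2),
              final = list(F1 = final$F1, F2 = final$F2),
              data = d, cfg = cfg, seed = seed)
  if (posthoc) {
    red <- drop_smallest_term(final$F1, final$F2, d$train)
    rfit <- retrain_coefficients(red$F1, red$F2, d$train, rcfg,
                                 maxit = cfg$retrain_maxit)
    out$model2 <- list(F1 = rfit$F1, F2 = rfit$F2, removed = red$removed)
  }
  out
}

#' Equation strings of a fitted bundle
#' @param bundle result of [run_example()].
#' @param stage `"final"`, `"sparse"` or `"expr"`.
#' @return named character vector.
#' @export
discovered_equations <- function(bundle, stage = "final") {
  st <- bundle[[stage]]
  c(F1 = format_expression(st$F1), F2 = format_expression(st$F2))
}
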