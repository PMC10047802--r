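## Hyperparameter selection for the regularization weights (lambda_M,
## lambda_S) by sequential search over the expanding-window average
## validation loss.

#' Expanding-window average validation loss
#'
#' For each curriculum stage (1 up to `Nt`), trains on the first `K r / Nt`
#' blocks of the training trajectories and evaluates the pure data-misfit
#' validation loss on the same block range of the validation trajectories;
#' returns the mean over stages.
#'
#' @param lambda_M,lambda_S regularization weights under evaluation.
#' @param train_ds,valid_ds training and validation `fp_dataset`s.
#' @param model an `fp_nnmodel` template (fresh weights are drawn per
#'   call with `seed`).
#' @param K,Nt schedule: total blocks and number of stages (`Nt` divides
#'   `K`).
#' @param seed initialization seed.
#' @param ... passed to [train()] (e.g. `maxit`, `substeps`, and the loss
#'   construction via `rollout`, `n_substeps`).
#' @param rollout,n_substeps block construction of the loss.
#' @return the scalar average validation loss (`Inf` when training aborts).
#' @export
expanding_validation_loss <- function(lambda_M, lambda_S, train_ds, valid_ds,
                                      model, K = train_ds$K, Nt = 5,
                                      seed = 1, rollout = "multi",
                                      n_substeps = 1, ...) {
  stopifnot(valid_ds$M > 0)
  cfg <- loss_config(lambda_M = lambda_M, lambda_S = lambda_S,
                     n_blocks = K, rollout = rollout,
                     n_substeps = n_substeps)
  tr <- tryCatch(
    train(train_ds, cfg, model, K = K, Nt = Nt, seed = seed,
          valid_ds = valid_ds, ...),
    error = function(e) NULL)
  if (is.null(tr) || any(!is.finite(tr$history$valid))) return(Inf)
  mean(tr$history$valid)
}

#' Select regularization weights by sequential search
#'
#' Seeded log-uniform random exploration of the `(lambda_M, lambda_S)`
#' box followed by a local refinement phase that samples around the best
#' trials so far (a simple sequential model-based strategy).  Returns the
#' minimizer and the full trial log.
#'
#' @param objective function `(lambda_M, lambda_S) -> scalar` to minimize
#'   (typically a closure over [expanding_validation_loss()]).
#' @param range_M,range_S search ranges (positive, log-uniform).
#' @param budget total number of trials (default 25).
#' @param seed integer seed; the trial sequence is reproducible.
#' @param explore_frac fraction of the budget spent on global exploration.
#' @return `list(lambda_M, lambda_S, value, trials)` with the trial log as
#'   a data frame.
#' @export
tune <- function(objective, range_M = c(1e-8, 1e-2),
                 range_S = c(1e-8, 1e-2), budget = 25, seed = 1,
                 explore_frac = 0.6) {
  stopifnot(budget >= 1, all(range_M > 0), all(range_S > 0))
  n_explore <- max(1, ceiling(explore_frac * budget))
  draws <- with_seed(seed, {
    lM <- exp(stats::runif(budget, log(range_M[1]), log(range_M[2])))
    lS <- exp(stats::runif(budget, log(range_S[1]), log(range_S[2])))
    jitter <- matrix(stats::rnorm(2 * budget, sd = 0.35), ncol = 2)
    pick <- sample.int(3, budget, replace = TRUE)
    list(lM = lM, lS = lS, jitter = jitter, pick = pick)
  })
  trials <- data.frame(trial = integer(0), lambda_M = numeric(0),
                       lambda_S = numeric(0), value = numeric(0))
  clamp <- function(x, r) pmin(pmax(x, r[1]), r[2])
  for (i in seq_len(budget)) {
    if (i <= n_explore || nrow(trials) == 0) {
      lM <- draws$lM[i]; lS <- draws$lS[i]
    } else {
      # refine around one of the best trials so far
      top <- trials[order(trials$value), , drop = FALSE]
      k <- min(draws$pick[i], nrow(top))
      lM <- clamp(exp(log(top$lambda_M[k]) + draws$jitter[i, 1]), range_M)
      lS <- clamp(exp(log(top$lambda_S[k]) + draws$jitter[i, 2]), range_S)
    }
    val <- objective(lM, lS)
    trials <- rbind(trials, data.frame(trial = i, lambda_M = lM,
                                       lambda_S = lS, value = val))
  }
  if (all(!is.finite(trials$value)))
    stop("tune: every trial failed (all objective values non-finite)")
  best <- trials[which.min(trials$value), ]
  list(lambda_M = best$lambda_M, lambda_S = best$lambda_S,
       value = best$value, trials = trials)
}
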