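## Post-hoc parsimony check: refit the model with its weakest interaction
## term removed and test, per time point, whether the two models'
## prediction-residual distributions differ.  Residual pairs (u, v) at each
## spatial grid point form a bivariate sample; the two-sample statistic is
## the Fasano-Franceschini orthant form of the Kolmogorov-Smirnov distance
## with a permutation null.

#' Remove the interaction term with the smallest L2 norm
#'
#' Computes `||coefficient * term column||_2` (discrete L2 over all
#' retained samples) for every interaction term -- diffusion terms are
#' never candidates -- and removes the smallest.  Ties remove the
#' later-listed term (with a message).
#'
#' @param F1,F2 `fp_expression` structures of the fitted model.
#' @param ds the observed `fp_dataset` the norms are measured on.
#' @return `list(F1, F2, removed, from)`: the reduced structure plus the
#'   label of the removed term.
#' @export
drop_smallest_term <- function(F1, F2, ds) {
  env <- dataset_env(ds, F1$alpha)
  w <- sqrt(space_weight(ds$grid))
  cand <- list()
  for (eq in 1:2) {
    Fx <- if (eq == 1) F1 else F2
    for (i in seq_along(Fx$terms)) {
      tm <- Fx$terms[[i]]
      if (is_diffusion_term(tm)) next
      nrm <- w * sqrt(sum((tm$coef * term_eval(tm, env))^2))
      cand[[length(cand) + 1]] <- list(eq = eq, i = i, norm = nrm,
                                       label = term_label(tm))
    }
  }
  if (length(cand) < 2)
    stop("drop_smallest_term needs at least two non-diffusion terms")
  norms <- vapply(cand, function(x) x$norm, 0)
  small <- which(norms <= min(norms) + 1e-15)
  if (length(small) > 1)
    message("drop_smallest_term: tie between term norms; removing the later-listed term")
  pick <- cand[[max(small)]]
  if (pick$eq == 1) F1$terms[[pick$i]] <- NULL else F2$terms[[pick$i]] <- NULL
  list(F1 = F1, F2 = F2, removed = pick$label, from = pick$eq)
}

is_diffusion_term <- function(tm) {
  is.null(tm$ratio) &&
    any(names(tm$pow) %in% c("uxx", "uyy", "vxx", "vyy")) &&
    length(tm$pow) == 1 && tm$pow[1] == 1
}

#' Two-sample bivariate Kolmogorov-Smirnov test (Fasano-Franceschini)
#'
#' For each origin point (taken from both samples) the plane is split into
#' four quadrants; the statistic is the average of the two one-sample-origin
#' maxima of `|F_A - F_B|` over quadrants.  The p-value comes from a seeded
#' permutation of the pooled sample.
#'
#' @param A,B numeric matrices with two columns (paired residuals).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation draw.
#' @return `list(statistic, p.value, n_perm)`.
#' @export
ks_two_sample <- function(A, B, n_perm = 999, seed = 1) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == 2, ncol(B) == 2, nrow(A) > 0, nrow(B) > 0)
  if (nrow(A) < 10 || nrow(B) < 10)
    warning("ks_two_sample: sample size below 10; p-value is unreliable")
  n1 <- nrow(A); n2 <- nrow(B); N <- n1 + n2
  X <- c(A[, 1], B[, 1]); Y <- c(A[, 2], B[, 2])
  # quadrant membership matrices over the pooled sample (origin = row)
  Xle <- outer(X, X, `<=`); Yle <- outer(Y, Y, `<=`)
  Q <- lapply(list(Xle & Yle, Xle & !Yle, !Xle & Yle, !(Xle | Yle)),
              function(M) matrix(as.numeric(M), N))
  memA <- c(rep(1, n1), rep(0, n2))
  # all permutations at once: membership matrix N x (n_perm + 1), first
  # column the observed labeling
  P <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample(memA), numeric(N))
  })
  P <- cbind(memA, P)
  colmax <- function(M) Reduce(pmax, asplit(M, 1))
  d <- numeric(ncol(P))
  for (M in Q) {
    FA <- (M %*% P) / n1
    FB <- (M %*% (1 - P)) / n2
    dif <- abs(FA - FB)
    stat <- (colmax(dif * P) + colmax(dif * (1 - P))) / 2
    d <- pmax(d, stat)
  }
  D <- d[1]
  p <- (1 + sum(d[-1] >= D - 1e-12)) / (1 + n_perm)
  list(statistic = D, p.value = p, n_perm = n_perm)
}

#' Multiple-testing adjustment with rejection counts
#'
#' Bonferroni, Holm step-down and Benjamini-Hochberg step-up adjustments
#' (via [stats::p.adjust()]), with rejections at level `alpha`.
#'
#' @param p vector of raw p-values.
#' @param alpha significance level (default 0.05).
#' @return data frame with raw and adjusted p-values and rejection flags.
#' @export
adjust_pvalues <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  out <- data.frame(
    p_raw = p,
    p_bonferroni = stats::p.adjust(p, "bonferroni"),
    p_holm = stats::p.adjust(p, "holm"),
    p_bh = stats::p.adjust(p, "BH"))
  out$reject_bonferroni <- out$p_bonferroni < alpha
  out$reject_holm <- out$p_holm < alpha
  out$reject_bh <- out$p_bh < alpha
  out
}

#' Per-time residual comparison of two fitted models
#'
#' Simulates both term-based models forward from the same initial state,
#' forms per-time residuals against the true trajectory, and runs a
#' two-sample bivariate K-S test at every time point on the paired
#' (u-residual, v-residual) values over (a spatial subsample of) the grid,
#' followed by the three multiplicity adjustments.
#'
#' @param model1,model2 `list(F1, F2)` sparse models.
#' @param truth `list(U, V, times)` true trajectory on the model grid,
#'   including `t = 0` in column/slice 1.
#' @param grid the [fp_grid()].
#' @param times indices (into `truth$times`, excluding the initial state)
#'   at which to test; defaults to all.
#' @param n_sub spatial subsample size per time point (keeps the
#'   permutation test affordable; seeded).
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @param dt_sim internal forward-Euler step for the model simulations
#'   (defaults to a diffusion-stable step).
#' @return `list(table, rejections, blown)`: per-time report in Table form
#'   plus rejection counts per adjustment method.
#' @export
posthoc_compare <- function(model1, model2, truth, grid, times = NULL,
                            n_sub = 100, n_perm = 999, seed = 1,
                            dt_sim = NULL) {
  nt <- length(truth$times) - 1
  if (is.null(times)) times <- seq_len(nt)
  sim1 <- predict_sparse(model1, truth$U[[1]], truth$V[[1]], grid,
                         times = truth$times, dt_sim = dt_sim)
  sim2 <- predict_sparse(model2, truth$U[[1]], truth$V[[1]], grid,
                         times = truth$times, dt_sim = dt_sim)
  npts <- length(truth$U[[1]])
  idx <- with_seed(seed, sample.int(npts, min(n_sub, npts)))
  p <- numeric(length(times))
  blown <- logical(length(times))
  for (j in seq_along(times)) {
    k <- times[j] + 1L
    if (!sim1$ok && k > length(sim1$U)) blown[j] <- TRUE
    if (!sim2$ok && k > length(sim2$U)) blown[j] <- TRUE
    if (blown[j]) { p[j] <- 0; next }   # a blown-up model counts as rejected
    E1 <- cbind(as.numeric(sim1$U[[k]])[idx] - as.numeric(truth$U[[k]])[idx],
                as.numeric(sim1$V[[k]])[idx] - as.numeric(truth$V[[k]])[idx])
    E2 <- cbind(as.numeric(sim2$U[[k]])[idx] - as.numeric(truth$U[[k]])[idx],
                as.numeric(sim2$V[[k]])[idx] - as.numeric(truth$V[[k]])[idx])
    p[j] <- ks_two_sample(E1, E2, n_perm = n_perm,
                          seed = seed + 1000L + j)$p.value
  }
  tab <- adjust_pvalues(p)
  tab <- cbind(time = truth$times[times + 1], tab)
  rej <- c(bonferroni = sum(tab$reject_bonferroni),
           holm = sum(tab$reject_holm),
           bh = sum(tab$reject_bh))
  list(table = tab, rejections = rej, blown = any(blown))
}
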