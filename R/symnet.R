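## Symbolic network over a library of gridded channels.
##
## The network takes the library vector L1 = (channels), and each hidden
## layer i computes a pair of learned linear combinations
##   (eta_i, xi_i) = W(i) L_i + b(i),
## combines them through a multiplication unit f_i = eta_i * xi_i or a
## division unit f_i = eta_i / xi_i, and appends f_i to the library:
## L_{i+1} = (L_i, f_i).  The output is a final linear read-out
## F = W(out) L_{k+1} + b(out).  Structural masks pin chosen weights at
## exactly zero: derivative channels never enter the nonlinear units, and
## division units are restricted to the form (linear in one species) /
## (quadratic in the other), which keeps every discovered rational term
## identifiable.  A trainable exponent channel u^alpha with
## alpha = 1.5 + 0.5 sin(eta) and a spatial-integral channel extend the
## library beyond polynomials.

#' Trainable fractional exponent
#'
#' `alpha = 1.5 + 0.5 * sin(eta)`, a smooth reparameterization keeping the
#' exponent inside `[1, 2]` for any real `eta`.
#'
#' @param eta unconstrained real parameter.
#' @return the exponent `alpha`.
#' @export
alpha_from_eta <- function(eta) 1.5 + 0.5 * sin(eta)

## ---- channel descriptors ------------------------------------------------

# A channel is computed from the smoothed fields u00 = D00 u, v00 = D00 v
# (and higher derivative filters).  Types: "deriv" (order >= 0), "square",
# "power" (u^alpha on the clamped base), "integral".
channel_spec <- function(name, dim) {
  field <- substr(name, 1, 1)
  if (name == "I")  return(list(name = name, field = "u", type = "integral"))
  if (name %in% c("ua", "va"))
    return(list(name = name, field = field, type = "power"))
  if (name %in% c("u2", "v2"))
    return(list(name = name, field = field, type = "square"))
  suff <- substring(name, 2)
  ord <- if (dim == 1) nchar(suff) else {
    c(sum(strsplit(suff, "")[[1]] == "x"), sum(strsplit(suff, "")[[1]] == "y"))
  }
  list(name = name, field = field, type = "deriv", order = ord)
}

# Symbolic content of a channel, as a polynomial in the base symbols.
channel_poly <- function(name) {
  switch(name,
         u2 = poly_var("u", 2),
         v2 = poly_var("v", 2),
         poly_var(name))
}

## ---- network object -----------------------------------------------------

#' Construct a symbolic network
#'
#' @param channels character vector of library channel names (order fixed;
#'   e.g. `c("u","uxx","uyy","v","vxx","vyy")`).
#' @param units character vector of hidden-unit kinds, `"mul"` or `"div"`.
#' @param mask_W list of 2-row logical matrices (one per unit) marking
#'   trainable weights; masked entries are pinned at exactly 0.
#' @param mask_b list of logical 2-vectors.
#' @param mask_out logical vector over `c(channels, units)` for the output
#'   read-out; `mask_bout` for its bias.
#' @param dim spatial dimension of the fields (1 or 2).
#' @param eps_div division safeguard: denominators are clamped to magnitude
#'   at least `eps_div` (sign preserved), so `f = eta / xi` is exact
#'   whenever `|xi| >= eps_div` and bounded otherwise.
#' @return object of class `fp_symnet` with zero-initialized weights.
#' @export
fp_symnet <- function(channels, units, mask_W, mask_b, mask_out,
                      mask_bout = TRUE, dim = 2, eps_div = 1e-6) {
  nch <- length(channels)
  k <- length(units)
  stopifnot(all(units %in% c("mul", "div")),
            length(mask_W) == k, length(mask_b) == k,
            length(mask_out) == nch + k)
  W <- vector("list", k); b <- vector("list", k)
  for (i in seq_len(k)) {
    stopifnot(nrow(mask_W[[i]]) == 2, ncol(mask_W[[i]]) == nch + i - 1)
    W[[i]] <- matrix(0, 2, nch + i - 1)
    b[[i]] <- c(0, 0)
  }
  structure(list(channels = channels, dim = dim,
                 specs = lapply(channels, channel_spec, dim = dim),
                 units = units, W = W, b = b,
                 Wout = numeric(nch + k), bout = 0,
                 mask_W = mask_W, mask_b = mask_b,
                 mask_out = mask_out, mask_bout = mask_bout,
                 eps_div = eps_div, pen_tau = 1e-3),
            class = "fp_symnet")
}

#' @export
print.fp_symnet <- function(x, ...) {
  cat(sprintf("<fp_symnet: %d channels (%s), units [%s], %d trainable weights>\n",
              length(x$channels), paste(x$channels, collapse = ","),
              paste(substr(x$units, 1, 1), collapse = ""),
              symnet_n_params(x)))
  invisible(x)
}

#' Number of unmasked trainable weights in a network
#' @param net an [fp_symnet()].
#' @return integer count (excludes any shared exponent parameter).
#' @export
symnet_n_params <- function(net) {
  as.integer(sum(vapply(net$mask_W, sum, 0L)) +
               sum(vapply(net$mask_b, sum, 0L)) +
               sum(net$mask_out) + sum(net$mask_bout))
}

symnet_get_params <- function(net) {
  out <- numeric(0)
  for (i in seq_along(net$units))
    out <- c(out, net$W[[i]][net$mask_W[[i]]], net$b[[i]][net$mask_b[[i]]])
  c(out, net$Wout[net$mask_out], if (net$mask_bout) net$bout)
}

symnet_set_params <- function(net, theta) {
  pos <- 0L
  takev <- function(k) {
    v <- theta[pos + seq_len(k)]; pos <<- pos + k; v
  }
  for (i in seq_along(net$units)) {
    net$W[[i]][] <- 0
    net$W[[i]][net$mask_W[[i]]] <- takev(sum(net$mask_W[[i]]))
    net$b[[i]][] <- 0
    net$b[[i]][net$mask_b[[i]]] <- takev(sum(net$mask_b[[i]]))
  }
  net$Wout[] <- 0
  net$Wout[net$mask_out] <- takev(sum(net$mask_out))
  net$bout <- if (net$mask_bout) takev(1L) else 0
  stopifnot(pos == length(theta))
  net
}

# Set weights explicitly (used for worked examples and tests); entries
# outside the masks may be set freely here -- masks only constrain training.
symnet_set_weights <- function(net, W = NULL, b = NULL, Wout = NULL,
                               bout = NULL) {
  if (!is.null(W)) for (i in seq_along(W)) net$W[[i]][] <- W[[i]]
  if (!is.null(b)) for (i in seq_along(b)) net$b[[i]][] <- b[[i]]
  if (!is.null(Wout)) net$Wout[] <- Wout
  if (!is.null(bout)) net$bout <- bout
  net
}

## ---- forward / backward -------------------------------------------------

# Safeguarded reciprocal denominator: sign(xi) * max(|xi|, eps); exact when
# |xi| >= eps.
safe_den <- function(xi, eps) {
  s <- ifelse(xi >= 0, 1, -1)
  s * pmax(abs(xi), eps)
}

#' Evaluate a symbolic network on a library of channel values
#'
#' @param net an [fp_symnet()].
#' @param lib named list of numeric arrays (one per channel, common shape).
#' @param want_cache keep intermediates for back-propagation.
#' @return the output array, or (with cache) `list(out, cache)` where
#'   `cache$penalty` is the division-safeguard penalty (mean shortfall of
#'   `|denominator|` below the safeguard trigger, summed over division
#'   units).
#' @export
symnet_forward <- function(net, lib, want_cache = FALSE) {
  L <- lib[net$channels]
  k <- length(net$units)
  etas <- xis <- xss <- vector("list", k)
  penalty <- 0
  for (i in seq_len(k)) {
    Wi <- net$W[[i]]; bi <- net$b[[i]]
    eta <- bi[1]; xi <- bi[2]
    for (c in seq_len(ncol(Wi))) {
      if (Wi[1, c] != 0) eta <- eta + Wi[1, c] * L[[c]]
      if (Wi[2, c] != 0) xi  <- xi  + Wi[2, c] * L[[c]]
    }
    if (length(eta) == 1) eta <- array(eta, dim_of(L[[1]]))
    if (length(xi) == 1)  xi  <- array(xi,  dim_of(L[[1]]))
    if (net$units[i] == "mul") {
      f <- eta * xi
      xs <- NULL
    } else {
      xs <- safe_den(xi, net$eps_div)
      f <- eta / xs
      penalty <- penalty + mean(pmax(net$pen_tau - abs(xi), 0)) / net$pen_tau
    }
    etas[[i]] <- eta; xis[[i]] <- xi; xss[[i]] <- xs
    L[[length(L) + 1]] <- f
  }
  out <- net$bout
  for (c in seq_along(L))
    if (net$Wout[c] != 0) out <- out + net$Wout[c] * L[[c]]
  if (length(out) == 1) out <- array(out, dim_of(L[[1]]))
  if (!want_cache) return(out)
  list(out = out,
       cache = list(L = L, etas = etas, xis = xis, xss = xss,
                    penalty = penalty))
}

dim_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# Vector-Jacobian product of the forward pass.  `gout` is the gradient of
# the loss w.r.t. the network output; `pen_w` the weight on the safeguard
# penalty.  Returns masked parameter gradients and the gradient w.r.t. each
# base channel.
symnet_backward <- function(net, cache, gout, pen_w = 0) {
  L <- cache$L
  nch <- length(net$channels)
  k <- length(net$units)
  gL <- vector("list", length(L))
  zero <- array(0, dim_of(L[[1]]))
  for (c in seq_along(L)) gL[[c]] <- zero
  gWout <- numeric(length(net$Wout)); gbout <- 0
  for (c in seq_along(L)) {
    if (net$mask_out[c]) gWout[c] <- sum(gout * L[[c]])
    if (net$Wout[c] != 0) gL[[c]] <- gL[[c]] + net$Wout[c] * gout
  }
  if (net$mask_bout) gbout <- sum(gout)
  gW <- lapply(net$W, function(w) w * 0)
  gb <- lapply(net$b, function(x) x * 0)
  npts <- prod(dim_of(L[[1]]))
  for (i in rev(seq_len(k))) {
    gf <- gL[[nch + i]]
    eta <- cache$etas[[i]]; xi <- cache$xis[[i]]
    if (net$units[i] == "mul") {
      geta <- gf * xi
      gxi <- gf * eta
    } else {
      xs <- cache$xss[[i]]
      geta <- gf / xs
      inside <- abs(xi) >= net$eps_div     # clamp region has zero xi-grad
      gxi <- -gf * eta / xs^2 * inside
      if (pen_w > 0) {
        trig <- abs(xi) < net$pen_tau
        gxi <- gxi - pen_w * ifelse(xi >= 0, 1, -1) * trig /
          (net$pen_tau * npts)
      }
    }
    Wi <- net$W[[i]]
    for (c in seq_len(ncol(Wi))) {
      if (net$mask_W[[i]][1, c]) gW[[i]][1, c] <- sum(geta * L[[c]])
      if (net$mask_W[[i]][2, c]) gW[[i]][2, c] <- sum(gxi * L[[c]])
      acc <- NULL
      if (Wi[1, c] != 0) acc <- Wi[1, c] * geta
      if (Wi[2, c] != 0) acc <- if (is.null(acc)) Wi[2, c] * gxi else
        acc + Wi[2, c] * gxi
      if (!is.null(acc)) gL[[c]] <- gL[[c]] + acc
    }
    if (net$mask_b[[i]][1]) gb[[i]][1] <- sum(geta)
    if (net$mask_b[[i]][2]) gb[[i]][2] <- sum(gxi)
  }
  list(gW = gW, gb = gb, gWout = gWout, gbout = gbout,
       gchannels = gL[seq_len(nch)])
}

# Flatten masked parameter gradients in the same order as
# symnet_get_params().
symnet_flatten_grads <- function(net, g) {
  out <- numeric(0)
  for (i in seq_along(net$units))
    out <- c(out, g$gW[[i]][net$mask_W[[i]]], g$gb[[i]][net$mask_b[[i]]])
  c(out, g$gWout[net$mask_out], if (net$mask_bout) g$gbout)
}

## ---- ready-made wirings -------------------------------------------------

# Rows of a unit-layer mask allowing the named channels (plus, optionally,
# previous unit outputs listed by index).
unit_mask <- function(channels, n_prev_units, row1, row2,
                      row1_units = integer(0), row2_units = integer(0)) {
  m <- matrix(FALSE, 2, length(channels) + n_prev_units)
  m[1, match(row1, channels)] <- TRUE
  m[2, match(row2, channels)] <- TRUE
  if (length(row1_units)) m[1, length(channels) + row1_units] <- TRUE
  if (length(row2_units)) m[2, length(channels) + row2_units] <- TRUE
  m
}

#' Network pair for the 2-D benchmark
#'
#' Library `(u, uxx, uyy, v, vxx, vyy)`.  Each equation gets one
#' multiplication unit building the quadratic polynomial part, a
#' multiplication unit building the quadratic denominator in `u`, a division
#' unit (linear in `u` over that quadratic), and a multiplication unit
#' coupling the fraction linearly in `v` -- the `l(v) r(u)` rational form.
#' The read-out spans the six channels, the polynomial unit, the
#' denominator-builder unit and the rational unit, plus a bias: 28
#' trainable weights per equation, 56 in total.  With `baseline = TRUE` the
#' division machinery is dropped and only the polynomial part remains (the
#' polynomial-only configuration).
#'
#' @param baseline polynomial-only variant.
#' @return `list(net1, net2)` of [fp_symnet()] objects.
#' @export
symnet_config_example1 <- function(baseline = FALSE) {
  ch <- c("u", "uxx", "uyy", "v", "vxx", "vyy")
  one <- function() {
    if (baseline) {
      units <- "mul"
      mW <- list(unit_mask(ch, 0, c("u", "v"), c("u", "v")))
      mb <- list(c(TRUE, TRUE))
      mout <- rep(TRUE, length(ch) + 1)
    } else {
      units <- c("mul", "mul", "div", "mul")
      mW <- list(
        unit_mask(ch, 0, c("u", "v"), c("u", "v")),          # quadratic part
        unit_mask(ch, 1, "u", "u"),                          # u-quadratic
        unit_mask(ch, 2, "u", "u", row2_units = 2L),         # lin(u)/quad(u)
        unit_mask(ch, 3, "v", character(0), row2_units = 3L) # l(v) * r(u)
      )
      mb <- list(c(TRUE, TRUE), c(TRUE, TRUE), c(TRUE, TRUE), c(TRUE, FALSE))
      mout <- c(rep(TRUE, length(ch)), TRUE, TRUE, FALSE, TRUE)
    }
    fp_symnet(ch, units, mW, mb, mout, dim = 2)
  }
  list(net1 = one(), net2 = one())
}

#' Network pair for the 1-D benchmark
#'
#' First equation: library `(u, ux, uxx, v, vx, vxx, I, ua)` with a
#' multiplication unit building the quadratic denominator in `v`, a division
#' unit (linear in `u` over that quadratic), and a multiplication unit
#' coupling `u^alpha` with the integral channel; read-out over
#' `(u, ux, uxx, v, vx, ua, f_I, f_div)` plus bias -- 21 trainable weights.
#' Second equation: purely linear read-out over
#' `(u, ux, uxx, v, vx, vxx)` plus bias -- 7 weights.  With the shared
#' exponent parameter `eta` this makes 29 trainable parameters.  With
#' `baseline = TRUE` both equations use the polynomial library only.
#'
#' @param baseline polynomial-only variant.
#' @return `list(net1, net2)`.
#' @export
symnet_config_example2 <- function(baseline = FALSE) {
  ch2 <- c("u", "ux", "uxx", "v", "vx", "vxx")
  net2 <- fp_symnet(ch2, character(0), list(), list(),
                    rep(TRUE, length(ch2)), dim = 1)
  if (baseline) {
    mW <- list(unit_mask(ch2, 0, c("u", "v"), c("u", "v")))
    net1 <- fp_symnet(ch2, "mul", mW, list(c(TRUE, TRUE)),
                      rep(TRUE, length(ch2) + 1), dim = 1)
    return(list(net1 = net1, net2 = net2))
  }
  ch1 <- c("u", "ux", "uxx", "v", "vx", "vxx", "I", "ua")
  mW <- list(
    unit_mask(ch1, 0, "v", "v"),                          # v-quadratic
    unit_mask(ch1, 1, "u", "v", row2_units = 1L),         # lin(u)/quad(v)
    unit_mask(ch1, 2, "ua", "I")                          # u^alpha * I
  )
  mb <- list(c(TRUE, TRUE), c(TRUE, TRUE), c(FALSE, TRUE))
  mout <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,  # channels
            FALSE, TRUE, TRUE)                                 # units
  net1 <- fp_symnet(ch1, c("mul", "div", "mul"), mW, mb, mout, dim = 1)
  list(net1 = net1, net2 = net2)
}

#' Five-hidden-layer demonstration network
#'
#' The generic wiring over the library
#' `(u, ux, uxx, v, vx, vxx, u2, v2, ua, I)` with unit kinds
#' multiply, divide, divide, multiply, multiply, used by the worked
#' expansion example and available as a general-purpose 1-D configuration.
#' Nonlinear units may touch every non-derivative channel and all previous
#' unit outputs; derivative channels enter only the read-out.
#'
#' @return an [fp_symnet()].
#' @export
symnet_config_demo <- function() {
  ch <- c("u", "ux", "uxx", "v", "vx", "vxx", "u2", "v2", "ua", "I")
  nonlin <- c("u", "v", "u2", "v2", "ua", "I")
  units <- c("mul", "div", "div", "mul", "mul")
  mW <- lapply(seq_along(units), function(i)
    unit_mask(ch, i - 1, nonlin, nonlin,
              row1_units = seq_len(i - 1), row2_units = seq_len(i - 1)))
  mb <- rep(list(c(TRUE, TRUE)), length(units))
  fp_symnet(ch, units, mW, mb, rep(TRUE, length(ch) + length(units)),
            dim = 1)
}

#' Instantiate the worked expansion example
#'
#' The five-layer demonstration network loaded with the printed weights:
#' `f1 = (u + v + 1)(u + v)`, `f2 = (v + 0.5)/(v^2 + 4v + 0.5)`,
#' `f3 = (0.5u + 1)/(u^2 + 0.2u)`, `f4 = 0.2 u f2`, `f5 = 0.2 v f3`, and
#' output `0.1u + 0.3uxx + 6v + f1 + 2 f4 + 3 f5`.
#'
#' @return an [fp_symnet()] with weights set.
#' @export
symnet_worked_example <- function() {
  net <- symnet_config_demo()
  e <- function(i, n) { v <- numeric(n); v[i] <- 1; v }
  W <- list(rbind(e(1, 10) + e(4, 10), e(1, 10) + e(4, 10)),
            rbind(e(4, 11), 4 * e(4, 11) + e(8, 11)),
            rbind(0.5 * e(1, 12), 0.2 * e(1, 12) + e(7, 12)),
            rbind(0.2 * e(1, 13), e(12, 13)),
            rbind(0.2 * e(4, 14), e(13, 14)))
  b <- list(c(1, 0), c(0.5, 0.5), c(1, 0), c(0, 0), c(0, 0))
  Wout <- 0.1 * e(1, 15) + 0.3 * e(3, 15) + 6 * e(4, 15) + e(11, 15) +
    2 * e(14, 15) + 3 * e(15, 15)
  symnet_set_weights(net, W = W, b = b, Wout = Wout, bout = 0)
}
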