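## Convolutional differential operators with trainable, partially
## constrained moment matrices.
##
## An N-point kernel q acts on a field by correlation,
##   (q (*) u)(x) = sum_k q[k] u(x + k dx),   k = -(N-1)/2 .. (N-1)/2,
## and its moment matrix
##   m_ij = (1 / (i! j!)) sum_{k1,k2} k1^i k2^j q[k1, k2]
## controls which mixed derivative the kernel approximates: if m_ij = 1 and
## all moments of total order <= i + j + 1 vanish except that one, then
## (q (*) u) / (dx^i dy^j) approximates d^{i+j} u / dx^i dy^j to at least
## second order.  Training a kernel through its moment matrix lets those
## low-order moments be pinned (the operator keeps its identity and accuracy
## order) while the remaining entries are free parameters.

# Linear map between kernels and moments: m = A q (1-D) with
# A[i+1, k] = offset_k^i / i!, offsets -(N-1)/2 .. (N-1)/2.
moment_basis <- function(N) {
  stopifnot(N %% 2 == 1)
  offs <- seq.int(-(N - 1) / 2, (N - 1) / 2)
  A <- outer(0:(N - 1), offs, function(i, k) k^i / factorial(i))
  A
}

#' Moment matrix of a convolution kernel
#'
#' Computes `m_ij = (1/(i! j!)) * sum k1^i k2^j q[k1, k2]` for a 2-D kernel
#' (rows indexed by the x-offset `k1`, columns by the y-offset `k2`), or the
#' moment vector `m_i` for a 1-D kernel.  Exact linear inverse of
#' [filter_from_moments()].
#'
#' @param q numeric kernel: an odd-length vector (1-D) or odd-sized square
#'   matrix (2-D), index origin at the center.
#' @return numeric vector/matrix of moments, same shape as `q`.
#' @examples
#' q <- matrix(0, 3, 3); q[3, 2] <- 1/2; q[1, 2] <- -1/2  # central diff in x
#' moments_from_filter(q)[2, 1]  # m_10 = 1
#' @export
moments_from_filter <- function(q) {
  if (is.matrix(q)) {
    stopifnot(nrow(q) == ncol(q), nrow(q) %% 2 == 1)
    A <- moment_basis(nrow(q))
    A %*% q %*% t(A)
  } else {
    A <- moment_basis(length(q))
    drop(A %*% q)
  }
}

#' Kernel realizing a prescribed moment matrix
#'
#' Solves the (Vandermonde-type, always nonsingular) linear system mapping
#' moments back to kernel entries.  Exact inverse of
#' [moments_from_filter()].
#'
#' @param M numeric moment vector (1-D) or square matrix (2-D).
#' @return the kernel, same shape as `M`.
#' @export
filter_from_moments <- function(M) {
  if (is.matrix(M)) {
    Ai <- solve(moment_basis(nrow(M)))
    Ai %*% M %*% t(Ai)
  } else {
    drop(solve(moment_basis(length(M)), M))
  }
}

# Constraint pattern for the derivative of multi-order `ord` (length 1 or 2):
# all moments of total order <= sum(ord) + 1 are fixed (Kronecker delta at
# `ord`), the rest are free.  This is the minimal pattern guaranteeing
# second-order accuracy.
moment_constraints <- function(N, ord) {
  if (length(ord) == 2) {
    tot <- outer(0:(N - 1), 0:(N - 1), `+`)
    fixed <- tot <= sum(ord) + 1
    M0 <- matrix(0, N, N)
    M0[ord[1] + 1, ord[2] + 1] <- 1
  } else {
    fixed <- (0:(N - 1)) <= ord + 1
    M0 <- numeric(N)
    M0[ord + 1] <- 1
  }
  list(M0 = M0, free = !fixed)
}

#' Bank of constrained trainable derivative filters
#'
#' One trainable kernel per derivative order.  For each order the moments of
#' total order `<= order + 1` are frozen to the values identifying that
#' derivative (second-order accuracy guarantee); higher moments are free
#' parameters, initialized at 0 so every kernel starts as an exact
#' finite-difference stencil.  Orders listed in `frozen` keep their free
#' moments pinned at 0 (exact stencils, no trainable entries).
#'
#' @param dim 1 or 2.
#' @param size odd kernel side length (e.g. 5 for 5x5 in 2-D, 19 for a 1x19
#'   row kernel in 1-D).
#' @param orders list of integer vectors: derivative orders, e.g.
#'   `list(c(0,0), c(2,0), c(0,2))` in 2-D or `list(0, 1, 2)` in 1-D.
#' @param dx grid spacing (`dx = dy` in 2-D).
#' @param frozen list of orders (subset of `orders`) excluded from training.
#' @return object of class `fp_filter_bank`.
#' @examples
#' bk <- fp_filter_bank(2, 5, list(c(0,0), c(2,0), c(0,2)), dx = 10/64)
#' bank_n_params(bk)  # 52
#' @export
fp_filter_bank <- function(dim, size, orders, dx, frozen = list()) {
  stopifnot(dim %in% c(1, 2), size %% 2 == 1)
  key <- function(o) paste0("D", paste0(o, collapse = ""))
  frozen_keys <- vapply(frozen, key, "")
  A1 <- moment_basis(size)
  Afull <- if (dim == 2) kronecker(A1, A1) else A1  # rows ~ vec(M), cols ~ vec(q)
  filters <- lapply(orders, function(o) {
    cs <- moment_constraints(size, o)
    fixed_rows <- which(!as.vector(cs$free))
    free_rows <- which(as.vector(cs$free))
    # trainable kernels are parameterized on an orthonormal basis of the
    # constraint null space, q = q0 + N z: the fixed moments are enforced
    # structurally and unit moves in z give O(1) kernel changes (the raw
    # moment coordinates of a wide kernel are catastrophically
    # ill-conditioned)
    Cmat <- Afull[fixed_rows, , drop = FALSE]
    Qfull <- qr.Q(qr(t(Cmat)), complete = TRUE)
    Nmat <- Qfull[, (length(fixed_rows) + 1):ncol(Qfull), drop = FALSE]
    q0 <- if (dim == 1) compact_stencil_1d(o, size) else
      as.vector(outer(compact_stencil_1d(o[1], size),
                      compact_stencil_1d(o[2], size)))
    Afree <- Afull[free_rows, , drop = FALSE]
    list(order = o,
         M0 = cs$M0,
         free = cs$free,
         theta = numeric(ncol(Nmat)),
         q0 = q0, Nmat = Nmat,
         mfree0 = drop(Afree %*% q0),
         Mmat = Afree %*% Nmat,
         trainable = !(key(o) %in% frozen_keys))
  })
  names(filters) <- vapply(orders, key, "")
  structure(list(dim = dim, N = size, dx = dx,
                 Ainv = solve(A1),
                 filters = filters),
            class = "fp_filter_bank")
}

compact_stencil_1d <- function(ord, N) {
  h <- (N - 1L) / 2L
  q <- numeric(N)
  core <- switch(as.character(ord),
                 "0" = 1,
                 "1" = c(-0.5, 0, 0.5),
                 "2" = c(1, -2, 1),
                 stop("no compact stencil for order ", ord))
  w <- (length(core) - 1L) / 2L
  q[(h + 1L - w):(h + 1L + w)] <- core
  q
}

#' @export
print.fp_filter_bank <- function(x, ...) {
  cat(sprintf("<fp_filter_bank %dD, %d-point kernels, %d trainable moments: %s>\n",
              x$dim, x$N, bank_n_params(x),
              paste(names(x$filters), collapse = " ")))
  invisible(x)
}

#' Number of trainable moment entries in a bank
#' @param bank an [fp_filter_bank()].
#' @return integer count.
#' @export
bank_n_params <- function(bank) {
  as.integer(sum(vapply(bank$filters, function(f)
    if (f$trainable) sum(f$free) else 0L, 0)))
}

# Training initialization: z = 0, i.e. every kernel starts as its embedded
# classical compact stencil (delta, [-1/2, 0, 1/2], [1, -2, 1]); these are
# exact second-order stencils whose spectral response (4/dx^2 for the
# second derivative) is the smallest of any consistent stencil, keeping
# explicit rollouts of diffusion as stable as they can be.
bank_init_theta <- function(bank) {
  numeric(sum(vapply(bank$filters, function(f)
    if (f$trainable) length(f$theta) else 0L, 0L)))
}

# Free moment entries of all trainable filters (the quantities the moment
# regularizer acts on), and the pull-back of a gradient over them onto the
# kernel parameters z.
bank_free_moments <- function(bank) {
  unlist(lapply(bank$filters, function(f) {
    if (!f$trainable) return(NULL)
    f$mfree0 + drop(f$Mmat %*% f$theta)
  }), use.names = FALSE)
}

bank_moment_grad <- function(bank, g) {
  out <- numeric(0)
  pos <- 0L
  for (f in bank$filters) {
    if (!f$trainable) next
    k <- nrow(f$Mmat)
    out <- c(out, drop(crossprod(f$Mmat, g[pos + seq_len(k)])))
    pos <- pos + k
  }
  stopifnot(pos == length(g))
  out
}

bank_get_theta <- function(bank) {
  unlist(lapply(bank$filters, function(f) if (f$trainable) f$theta else NULL),
         use.names = FALSE)
}

bank_set_theta <- function(bank, theta) {
  pos <- 0L
  for (nm in names(bank$filters)) {
    f <- bank$filters[[nm]]
    if (!f$trainable) next
    k <- sum(f$free)
    bank$filters[[nm]]$theta <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  stopifnot(pos == length(theta))
  bank
}

# Full moment matrix of one filter: the fixed pattern exactly, free
# entries computed from the current kernel.
bank_moments <- function(bank, name) {
  f <- bank$filters[[name]]
  M <- f$M0
  M[f$free] <- f$mfree0 + drop(f$Mmat %*% f$theta)
  M
}

# Kernel of one filter: q = q0 + N z in the constraint null space.
bank_kernel <- function(bank, name) {
  f <- bank$filters[[name]]
  q <- f$q0 + drop(f$Nmat %*% f$theta)
  if (bank$dim == 2) matrix(q, bank$N, bank$N) else q
}

## ---- mirror padding and correlation, batched over a trailing dimension ----

# 1-D fields are stored as n x M matrices (M trajectories); 2-D fields as
# n x n x M arrays.  Mirror (even) reflection pads h = (N-1)/2 ghost cells:
# the k-th ghost cell outside a face copies the k-th interior cell inside it,
# which is the cell-centered discretization of a zero-flux boundary.

mirror_pad_1d <- function(U, h) {
  n <- nrow(U)
  U[c(h:1, 1:n, n:(n - h + 1)), , drop = FALSE]
}

mirror_pad_2d <- function(U, h) {
  n <- dim(U)[1]
  idx <- c(h:1, 1:n, n:(n - h + 1))
  U[idx, idx, , drop = FALSE]
}

# Correlation out(i) = sum_k q[k] Upad(i + k + h), batched.
conv1d_mirror <- function(U, q) {
  n <- nrow(U); N <- length(q); h <- (N - 1L) / 2L
  Up <- mirror_pad_1d(U, h)
  out <- matrix(0, n, ncol(U))
  for (k in seq_len(N))           # offset k - 1 - h
    out <- out + q[k] * Up[(k - 1L) + 1:n, , drop = FALSE]
  out
}

conv2d_mirror <- function(U, Q) {
  n <- dim(U)[1]; N <- nrow(Q); h <- (N - 1L) / 2L
  Up <- mirror_pad_2d(U, h)
  out <- array(0, dim(U))
  for (k1 in seq_len(N)) for (k2 in seq_len(N)) {
    if (Q[k1, k2] == 0) next
    out <- out + Q[k1, k2] * Up[(k1 - 1L) + 1:n, (k2 - 1L) + 1:n, , drop = FALSE]
  }
  out
}

# Fold a padded-array gradient back onto interior cells (adjoint of mirror
# padding).
fold_pad_1d <- function(Gp, n, h) {
  G <- Gp[h + 1:n, , drop = FALSE]
  G[1:h, ] <- G[1:h, , drop = FALSE] + Gp[h:1, , drop = FALSE]
  G[n:(n - h + 1), ] <- G[n:(n - h + 1), , drop = FALSE] +
    Gp[(h + n) + 1:h, , drop = FALSE]
  G
}

fold_pad_2d <- function(Gp, n, h) {
  ix <- h + 1:n
  G <- Gp[ix, , , drop = FALSE]
  G[1:h, , ] <- G[1:h, , , drop = FALSE] + Gp[h:1, , , drop = FALSE]
  G[n:(n - h + 1), , ] <- G[n:(n - h + 1), , , drop = FALSE] +
    Gp[(h + n) + 1:h, , , drop = FALSE]
  G2 <- G[, ix, , drop = FALSE]
  G2[, 1:h, ] <- G2[, 1:h, , drop = FALSE] + G[, h:1, , drop = FALSE]
  G2[, n:(n - h + 1), ] <- G2[, n:(n - h + 1), , drop = FALSE] +
    G[, (h + n) + 1:h, , drop = FALSE]
  G2
}

# Adjoint of conv*_mirror with respect to the input field.
conv1d_mirror_adj <- function(G, q, n) {
  N <- length(q); h <- (N - 1L) / 2L
  Gp <- matrix(0, n + 2L * h, ncol(G))
  for (k in seq_len(N))
    Gp[(k - 1L) + 1:n, ] <- Gp[(k - 1L) + 1:n, , drop = FALSE] + q[k] * G
  fold_pad_1d(Gp, n, h)
}

conv2d_mirror_adj <- function(G, Q, n) {
  N <- nrow(Q); h <- (N - 1L) / 2L
  M <- dim(G)[3]
  Gp <- array(0, c(n + 2L * h, n + 2L * h, M))
  for (k1 in seq_len(N)) for (k2 in seq_len(N)) {
    if (Q[k1, k2] == 0) next
    Gp[(k1 - 1L) + 1:n, (k2 - 1L) + 1:n, ] <-
      Gp[(k1 - 1L) + 1:n, (k2 - 1L) + 1:n, , drop = FALSE] + Q[k1, k2] * G
  }
  fold_pad_2d(Gp, n, h)
}

# Gradient of sum(G * conv(U, q)) with respect to kernel entries.
conv1d_kernel_grad <- function(G, U, N) {
  n <- nrow(U); h <- (N - 1L) / 2L
  Up <- mirror_pad_1d(U, h)
  vapply(seq_len(N), function(k) sum(G * Up[(k - 1L) + 1:n, , drop = FALSE]), 0)
}

conv2d_kernel_grad <- function(G, U, N) {
  n <- dim(U)[1]; h <- (N - 1L) / 2L
  Up <- mirror_pad_2d(U, h)
  gq <- matrix(0, N, N)
  for (k1 in seq_len(N)) for (k2 in seq_len(N))
    gq[k1, k2] <- sum(G * Up[(k1 - 1L) + 1:n, (k2 - 1L) + 1:n, , drop = FALSE])
  gq
}

# Pull a kernel gradient back to the kernel parameters z of one filter.
kernel_grad_to_theta <- function(bank, name, gq) {
  f <- bank$filters[[name]]
  drop(crossprod(f$Nmat, as.vector(gq)))
}

#' Apply a constrained derivative filter to a field
#'
#' Mirror-pads the field (Neumann-consistent), correlates with the kernel
#' built from the filter's constrained moment matrix, and scales by
#' `1 / dx^i` (`1 / (dx^i dy^j)` in 2-D).
#'
#' @param bank an [fp_filter_bank()].
#' @param order integer vector: derivative order, e.g. `c(2, 0)` or `1`.
#' @param values field values: vector / matrix in 1-D (columns = batch),
#'   matrix / 3-d array in 2-D.
#' @return array of the same shape as `values`.
#' @export
apply_derivative <- function(bank, order, values) {
  nm <- paste0("D", paste0(order, collapse = ""))
  stopifnot(nm %in% names(bank$filters))
  q <- bank_kernel(bank, nm)
  scale <- bank$dx^sum(order)
  if (bank$dim == 1) {
    v <- if (is.matrix(values)) values else matrix(values, ncol = 1)
    out <- conv1d_mirror(v, q) / scale
    if (is.matrix(values)) out else drop(out)
  } else {
    v <- if (length(dim(values)) == 3) values else
      array(values, c(dim(values), 1))
    out <- conv2d_mirror(v, q) / scale
    if (length(dim(values)) == 3) out else out[, , 1]
  }
}

#' Spatial integral channel
#'
#' Quadrature of a 1-D field over its full extent: `dx * sum(u)`, the
#' composite rule exact for constants on a cell-centered grid with mirror
#' boundary closure (equivalently the trapezoid rule applied to the
#' mirror-extended field).  Returns one scalar per batch column.
#'
#' @param values numeric vector (one field) or `n x M` matrix (batch).
#' @param grid an [fp_grid()] with `dim == 1`.
#' @return scalar, or length-`M` vector for a batch.
#' @export
integral_operator <- function(values, grid) {
  stopifnot(grid$dim == 1)
  if (is.matrix(values)) grid$dx * colSums(values)
  else grid$dx * sum(values)
}
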