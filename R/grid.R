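#' Uniform spatial grid
#'
#' A cell-centered uniform grid in one or two space dimensions.  The spacing
#' is `(right - left) / n`, and grid points sit at cell centers
#' `left + (i - 1/2) * dx`.  All fields handled by the package live on such a
#' grid, and the mirror (even-reflection) boundary treatment used throughout
#' is the discrete counterpart of homogeneous Neumann (no-flux) boundary
#' conditions.
#'
#' @param xlim length-2 numeric, the spatial extent along x.
#' @param n number of grid points per axis (same along x and y in 2-D).
#' @param dim 1 or 2.
#' @param ylim extent along y; defaults to `xlim` (2-D only).
#' @return An object of class `fp_grid` with elements `dim`, `xlim`, `ylim`,
#'   `n`, `dx`, and the cell-center coordinates `x` (and `y` in 2-D).
#' @examples
#' g <- fp_grid(c(-5, 5), 64, dim = 2)
#' g$dx  # 10/64
#' @export
fp_grid <- function(xlim, n, dim = 2, ylim = xlim) {
  stopifnot(length(xlim) == 2, xlim[2] > xlim[1], n >= 3, dim %in% c(1, 2))
  dx <- (xlim[2] - xlim[1]) / n
  g <- list(dim = dim, xlim = xlim, n = as.integer(n), dx = dx,
            x = xlim[1] + (seq_len(n) - 0.5) * dx)
  if (dim == 2) {
    stopifnot(abs((ylim[2] - ylim[1]) / n - dx) < 1e-12)
    g$ylim <- ylim
    g$y <- ylim[1] + (seq_len(n) - 0.5) * dx
  }
  class(g) <- "fp_grid"
  g
}

#' @export
print.fp_grid <- function(x, ...) {
  cat(sprintf("<fp_grid %dD: %d points/axis on [%g, %g], dx = %g>\n",
              x$dim, x$n, x$xlim[1], x$xlim[2], x$dx))
  invisible(x)
}

#' Field snapshot
#'
#' One scalar field on a grid at one time.  `values` is a length-`n` vector
#' (1-D) or an `n x n` matrix (2-D).
#'
#' @param values numeric vector or matrix of field values.
#' @param grid an [fp_grid()].
#' @param time scalar time stamp.
#' @return An object of class `fp_field`.
#' @export
fp_field <- function(values, grid, time = 0) {
  if (grid$dim == 1) {
    values <- as.numeric(values)
    stopifnot(length(values) == grid$n)
  } else {
    stopifnot(is.matrix(values), all(dim(values) == grid$n))
  }
  stopifnot(all(is.finite(values)))
  structure(list(values = values, grid = grid, time = time),
            class = "fp_field")
}

## Discrete L2 norm convention used everywhere in the package:
## ||f||_2^2 = dx * sum(f^2) in 1-D and dx*dy * sum(f^2) in 2-D.
space_weight <- function(grid) grid$dx^grid$dim

#' Discrete L2 norm of a gridded field
#'
#' `||f||_2^2 = dx * sum(f^2)` in 1-D, `dx * dy * sum(f^2)` in 2-D.  This is
#' the convention used in the training loss, in the L2-norm term selection
#' criterion, and in the reported prediction errors.
#'
#' @param values numeric array of field values.
#' @param grid an [fp_grid()].
#' @return the scalar norm.
#' @export
discrete_l2 <- function(values, grid) {
  sqrt(space_weight(grid) * sum(values^2))
}
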