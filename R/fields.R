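#' Periodic grid specification
#'
#' Describes the discretized habitat: a ring of `cells` cells in 1D or a
#' `cells` x `cells` torus in 2D, with grid spacing `spacing` (in units of the
#' scale of altruism).  Individual positions are integer cell indices
#' (0-based); physical coordinate = index * spacing.
#'
#' @param cells Number of cells per side (positive integer).
#' @param spacing Cell size `dx` in length units.
#' @param dim Habitat dimension, 1 or 2.
#' @return An object of class `grid_spec` with elements `cells_per_side`,
#'   `spacing`, `dim`, `length` (habitat side `L = cells * spacing`) and
#'   `n_cells` (total number of cells).
#' @export
grid_spec <- function(cells, spacing, dim = 1L) {
  cells <- as.integer(cells)
  if (cells < 2L) stop("grid must have at least 2 cells per side")
  if (!dim %in% c(1L, 2L)) stop("dim must be 1 or 2")
  if (spacing <= 0) stop("spacing must be positive")
  structure(
    list(cells_per_side = cells, spacing = spacing, dim = as.integer(dim),
         length = cells * spacing, n_cells = as.integer(cells^dim)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> dim=%d, %d cells/side, dx=%g, L=%g\n",
              x$dim, x$cells_per_side, x$spacing, x$length))
  invisible(x)
}

#' Scalar field on a periodic grid
#'
#' @param values Numeric vector (1D) or matrix (2D) of per-cell values.
#' @param grid A [grid_spec()].
#' @param units Optional unit label carried along for documentation.
#' @return A `scalar_field` object.
#' @export
scalar_field <- function(values, grid, units = NULL) {
  if (grid$dim == 2L && is.matrix(values)) values <- as.vector(values)
  if (length(values) != grid$n_cells) stop("value count does not match grid")
  if (!all(is.finite(values))) stop("field values must be finite")
  structure(list(values = as.numeric(values), grid = grid, units = units),
            class = "scalar_field")
}

field_values <- function(x) if (inherits(x, "scalar_field")) x$values else as.numeric(x)

#' Discretized, periodically wrapped Gaussian kernel
#'
#' Samples the Gaussian density with standard deviation `sigma` at cell-centre
#' offsets, sums over periodic images, and renormalizes so that
#' `sum(values) * dx^dim == 1` exactly.  The result is the kernel used for all
#' kernel density estimates (local density, public good, smoothed density).
#'
#' @param sigma Kernel standard deviation (length units); must be positive.
#' @param grid A [grid_spec()].
#' @return A `scalar_field` whose value at cell offset `j` is the wrapped
#'   kernel density at displacement `j * dx` (indices wrap, so the entry at
#'   `X - j` equals the entry at `j`).
#' @export
gaussian_kernel <- function(sigma, grid) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  L <- grid$length
  if (6 * sigma > L) {
    warning("kernel sigma is large relative to the habitat (6*sigma > L)")
  }
  X <- grid$cells_per_side
  dx <- grid$spacing
  offs <- (0:(X - 1)) * dx
  n_img <- max(1L, ceiling(6 * sigma / L))
  k1 <- numeric(X)
  for (mimg in -n_img:n_img) k1 <- k1 + dnorm(offs + mimg * L, sd = sigma)
  if (grid$dim == 1L) {
    vals <- k1 / (sum(k1) * dx)
  } else {
    k2 <- outer(k1, k1)
    vals <- k2 / (sum(k2) * dx^2)
  }
  scalar_field(vals, grid, units = sprintf("1/length^%d", grid$dim))
}

#' Exact circular convolution on the periodic grid
#'
#' Implemented via the discrete Fourier transform; the result equals the
#' direct wrap-around summation up to round-off.
#'
#' @param occ Per-cell values (numeric vector/matrix or `scalar_field`).
#' @param kernel Kernel `scalar_field` on the same grid.
#' @param grid The shared [grid_spec()] (taken from `kernel` if missing).
#' @return A `scalar_field` with the convolved values.
#' @export
circular_convolve <- function(occ, kernel, grid = kernel$grid) {
  v <- field_values(occ)
  k <- field_values(kernel)
  if (length(v) != length(k)) stop("occupancy and kernel grids do not match")
  if (grid$dim == 1L) {
    out <- Re(fft(fft(v) * fft(k), inverse = TRUE)) / length(v)
  } else {
    X <- grid$cells_per_side
    vm <- matrix(v, X, X)
    km <- matrix(k, X, X)
    out <- Re(fft(fft(vm) * fft(km), inverse = TRUE)) / length(v)
  }
  scalar_field(out, grid)
}

#' Per-cell occupancy of a population state
#'
#' @param state A population state data frame (see [init_population()]).
#' @param grid A [grid_spec()].
#' @param weights Optional per-individual weights (e.g. effective traits);
#'   default counts individuals.
#' @return Numeric vector of length `grid$n_cells` (column-major in 2D).
#' @export
occupancy <- function(state, grid, weights = NULL) {
  idx <- state_linear_cells(state, grid)
  out <- numeric(grid$n_cells)
  if (is.null(weights)) {
    out <- as.numeric(tabulate(idx + 1L, nbins = grid$n_cells))
  } else if (length(idx)) {
    agg <- rowsum(as.numeric(weights), group = idx)
    out[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  }
  out
}

state_linear_cells <- function(state, grid) {
  X <- grid$cells_per_side
  if (grid$dim == 1L) {
    idx <- state$cell_x
  } else {
    idx <- state$cell_x + X * state$cell_y
  }
  if (any(idx < 0L | idx >= grid$n_cells)) stop("individual positions fall off the grid")
  as.integer(idx)
}

#' Local population density field
#'
#' The kernel density estimate `D(y) = sum_i G(x_i - y; sigma)` evaluated at
#' every grid cell (units count/length^dim), with periodic wrap-around.
#'
#' @param state Population state data frame.
#' @param sigma Kernel bandwidth, typically the scale of competition.
#' @param grid A [grid_spec()].
#' @return A `scalar_field`.
#' @export
density_field <- function(state, sigma, grid) {
  occ <- occupancy(state, grid)
  circular_convolve(occ, gaussian_kernel(sigma, grid), grid)
}

#' Public-good field
#'
#' The trait-weighted kernel density estimate
#' `A(y) = sum_i phiE_i G(x_i - y; sigma)`, where `phiE = max(phi, 0)` is the
#' effective trait.  Linear in the trait vector.
#'
#' @param state Population state data frame with a `phi` column.
#' @param sigma Kernel bandwidth, typically the scale of altruism (1).
#' @param grid A [grid_spec()].
#' @return A `scalar_field`.
#' @export
public_good_field <- function(state, sigma, grid) {
  w <- pmax(state$phi, 0)
  occ <- occupancy(state, grid, weights = w)
  circular_convolve(occ, gaussian_kernel(sigma, grid), grid)
}

#' Export a scalar field as a table
#'
#' @param field A `scalar_field`.
#' @return A data frame with cell indices, physical coordinates, and values.
#' @export
field_table <- function(field) {
  g <- field$grid
  X <- g$cells_per_side
  if (g$dim == 1L) {
    data.frame(cell = 0:(X - 1), x = (0:(X - 1)) * g$spacing, value = field$values)
  } else {
    ix <- rep(0:(X - 1), times = X)
    iy <- rep(0:(X - 1), each = X)
    data.frame(cell_x = ix, cell_y = iy,
               x = ix * g$spacing, y = iy * g$spacing, value = field$values)
  }
}
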