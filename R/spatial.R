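#' Radial distribution function on a 1D periodic grid
#'
#' Observed ordered pair counts `O(r)` at separation `r = k*dx` (from the
#' circular autocorrelation of the occupancy vector) normalized by the
#' uniform-random expectation `E(r) = n^2 / X`; self-pairs (`r = 0`) are
#' excluded.
#'
#' @param state 1D population state, or a numeric occupancy vector.
#' @param grid A [grid_spec()].
#' @param r_max Largest separation reported (default `L / 2`).
#' @return Data frame with `r`, `O`, `E`, `g`.
#' @export
rdf_1d <- function(state, grid, r_max = grid$length / 2) {
  occ <- if (is.numeric(state)) state else occupancy(state, grid)
  n <- sum(occ)
  if (n < 2) stop("need at least two individuals for a pair distribution")
  X <- grid$cells_per_side
  ac <- Re(fft(Mod(fft(occ))^2, inverse = TRUE)) / X  # ordered pairs per offset
  kmax <- min(X - 1L, floor(r_max / grid$spacing))
  k <- seq_len(kmax)
  O <- ac[k + 1L]
  E <- n^2 / X
  data.frame(r = k * grid$spacing, O = O, E = E, g = O / E)
}

#' Distance multiplicities on a square grid
#'
#' Number of integer offsets `(a, b)` (both signs, excluding the origin)
#' realizing each admissible squared distance `a^2 + b^2 <= r_max^2/dx^2`.
#' E.g. distance `5*dx` (12 offsets) occurs three times as often as `6*dx`
#' (4 offsets).
#'
#' @param r_max_cells Largest offset radius, in cells.
#' @return Data frame with `r_cells` (sorted) and multiplicity `F`.
#' @export
grid_multiplicity <- function(r_max_cells) {
  amax <- floor(r_max_cells)
  a <- -amax:amax
  off <- expand.grid(a = a, b = a)
  off <- off[off$a != 0 | off$b != 0, ]
  r2 <- off$a^2 + off$b^2
  r2 <- r2[r2 <= r_max_cells^2]
  tab <- table(r2)
  data.frame(r_cells = sqrt(as.numeric(names(tab))), F = as.integer(tab))
}

#' Radial distribution function on a 2D periodic grid
#'
#' Ordered pair counts from the 2D circular autocorrelation, grouped by the
#' admissible distances `r^2 = (a^2 + b^2) dx^2`; the random expectation
#' `E(r) = F(r) n^2 / X^2` accounts for the multiplicity `F(r)` of each
#' distance on the square grid.  Optionally binned for plotting.
#'
#' @param state 2D population state, or an occupancy matrix.
#' @param grid A [grid_spec()] with `dim = 2`.
#' @param r_max Largest separation (default `L / 2`).
#' @param bin_width If not `NULL`, bin `g(r)` into linear bins of this width
#'   (default `dx * sqrt(2)`); pair counts are aggregated before the ratio.
#' @return Data frame with `r`, `F`, `O`, `E`, `g` (unbinned), or `r`
#'   (bin centre), `O`, `E`, `g` when binned.
#' @export
rdf_2d <- function(state, grid, r_max = grid$length / 2,
                   bin_width = grid$spacing * sqrt(2)) {
  X <- grid$cells_per_side
  occ <- if (is.matrix(state)) state else matrix(occupancy(state, grid), X, X)
  n <- sum(occ)
  if (n < 2) stop("need at least two individuals for a pair distribution")
  ac <- Re(fft(Mod(fft(occ))^2, inverse = TRUE)) / X^2
  kmax <- min(floor(X / 2), floor(r_max / grid$spacing))
  ia <- 0:(X - 1)
  da <- pmin(ia, X - ia)
  dmat <- outer(da^2, da^2, `+`)  # squared offset distance in cells
  keep <- dmat > 0 & dmat <= kmax^2
  r2 <- dmat[keep]
  O_all <- ac[keep]
  Otab <- rowsum(O_all, r2)
  Ftab <- rowsum(rep(1, length(r2)), r2)
  r <- sqrt(as.numeric(rownames(Otab))) * grid$spacing
  ord <- order(r)
  r <- r[ord]
  Fr <- Ftab[ord, 1L]
  O <- Otab[ord, 1L]
  E <- Fr * n^2 / X^2
  if (is.null(bin_width)) {
    return(data.frame(r = r, F = Fr, O = O, E = E, g = O / E))
  }
  bin <- floor(r / bin_width)
  Ob <- rowsum(O, bin)
  Eb <- rowsum(E, bin)
  data.frame(r = (as.numeric(rownames(Ob)) + 0.5) * bin_width,
             O = Ob[, 1L], E = Eb[, 1L], g = Ob[, 1L] / Eb[, 1L])
}

#' Spatial variance of the smoothed density
#'
#' Variance over grid cells of the bandwidth-`sigma_a/2` kernel density
#' estimate; a flat (well-mixed) population gives a value near zero, strong
#' colony patterns give large values.
#'
#' @param state Population state data frame.
#' @param grid A [grid_spec()].
#' @param bandwidth Smoothing bandwidth (default 0.5).
#' @return The spatial variance (density^2 units).
#' @export
density_variance <- function(state, grid, bandwidth = 0.5) {
  kde <- density_field(state, bandwidth, grid)
  v <- kde$values
  mean(v^2) - mean(v)^2
}

#' Dominant spatial mode of the smoothed density
#'
#' Discrete Fourier transform of the bandwidth-`sigma_a/2` KDE; the nonzero
#' wavenumber with the largest amplitude is converted to a wavelength
#' `L / k`.
#'
#' @param state 1D population state.
#' @param grid A [grid_spec()].
#' @param bandwidth Smoothing bandwidth (default 0.5).
#' @return List with `wavelength`, `wavenumber`, `amplitude`; `NA` (flagged
#'   by `flat = TRUE`) for a numerically flat field.
#' @export
dominant_mode <- function(state, grid, bandwidth = 0.5) {
  kde <- density_field(state, bandwidth, grid)
  v <- kde$values
  sp <- Mod(fft(v))
  X <- length(v)
  amp <- sp[2:floor(X / 2 + 1)]
  if (max(amp) <= 1e-10 * max(sp[1], 1)) {
    return(list(wavelength = NA_real_, wavenumber = NA_integer_,
                amplitude = NA_real_, flat = TRUE))
  }
  k <- which.max(amp)
  list(wavelength = grid$length / k, wavenumber = k,
       amplitude = 2 * amp[k] / X, flat = FALSE)
}

#' Hexagonal lattice constant from a colony count
#'
#' A hexagonal (triangular) lattice has node density `2 / (sqrt(3) a^2)`, so
#' `nu` colonies in a periodic square habitat of side `L` imply a lattice
#' constant `a = sqrt(2 L^2 / (sqrt(3) nu))`.
#'
#' @param nu Number of colonies (lattice nodes), >= 1.
#' @param L Habitat side length.
#' @return Estimated lattice constant `a`.
#' @export
lattice_constant_from_count <- function(nu, L) {
  if (nu < 1 || L <= 0) stop("nu must be >= 1 and L positive")
  sqrt(2 * L^2 / (sqrt(3) * nu))
}

#' Colony count implied by a hexagonal lattice constant
#' @param a Lattice constant.
#' @param L Habitat side length.
#' @return Expected node count `nu = 2 L^2 / (sqrt(3) a^2)`.
#' @export
lattice_count_from_constant <- function(a, L) {
  2 * L^2 / (sqrt(3) * a^2)
}
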