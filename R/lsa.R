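#' Homogeneous equilibrium density
#'
#' The positive density `rho0` at which a spatially uniform population with
#' fixed trait `phi` neither grows nor shrinks, i.e. the root of
#' `g0 * (1 - c*phi + b_max*phi*rho/(b_max/b0 + phi*rho)) * (1 - rho/K) = d`
#' on `(0, K)`.  Independent of the motility constant.  For defectors
#' (`phi = 0`) this reduces to `(1 - d/g0) * K`.
#'
#' @param params A [sim_params()] object.
#' @param phi Fixed trait value (>= 0).
#' @return The equilibrium density, or `NA` (with attribute
#'   `viable = FALSE`) when no positive equilibrium exists.
#' @export
homogeneous_equilibrium <- function(params, phi) {
  if (phi < 0) stop("phi must be nonnegative")
  f <- function(rho) {
    params$g0 *
      (1 - params$c * phi +
         params$b_max * phi * rho / (params$b_max / params$b0 + phi * rho)) *
      (1 - rho / params$K) - params$d
  }
  eps <- params$K * 1e-12
  grid <- seq(eps, params$K - eps, length.out = 512)
  vals <- vapply(grid, f, numeric(1))
  sgn <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (!length(sgn)) {
    out <- NA_real_
    attr(out, "viable") <- FALSE
    return(out)
  }
  # the relevant equilibrium is the largest root (stable branch)
  i <- sgn[length(sgn)]
  uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
}

#' Growth eigenvalue of a periodic perturbation
#'
#' The linear growth rate `E(lambda)` of a sinusoidal density perturbation of
#' wavelength `lambda` around the homogeneous equilibrium, for a population
#' with fixed trait `phi`.  It is the sum of a positive altruism term
#' (suppressed for `lambda << sigma_a`), a negative motility term
#' (strong for `lambda << sigma_m`), and a negative resource-competition term
#' (suppressed for `lambda << sigma_rc`):
#' \deqn{E(\lambda) = \frac{g_0 (b_{max}^2/b_0)\,\phi\rho_0 (1-\rho_0/K)}
#'   {(b_{max}/b_0 + \phi\rho_0)^2} e^{-2(\pi\sigma_a/\lambda)^2}
#'   - 2 d (\pi\sigma_m/\lambda)^2
#'   - \frac{d\rho_0/K}{1-\rho_0/K} e^{-2(\pi\sigma_{rc}/\lambda)^2}.}
#'
#' @param lambda Perturbation wavelength(s), > 0.
#' @param phi Fixed trait value.
#' @param params A [sim_params()] object.
#' @param rho0 Optional precomputed equilibrium density.
#' @return `E(lambda)`, vectorized over `lambda`.
#' @export
growth_eigenvalue <- function(lambda, phi, params, rho0 = NULL) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (is.null(rho0)) rho0 <- homogeneous_equilibrium(params, phi)
  if (!is.finite(rho0)) stop("no positive homogeneous equilibrium at this phi")
  if (rho0 >= params$K) stop("equilibrium density equals K; eigenvalue degenerate")
  sig_m <- params$sigma_m
  altr <- params$g0 * (params$b_max^2 / params$b0) * phi * rho0 *
    (1 - rho0 / params$K) / (params$b_max / params$b0 + phi * rho0)^2
  altr * exp(-2 * (pi * params$sigma_a / lambda)^2) -
    2 * params$d * (pi * sig_m / lambda)^2 -
    (params$d * rho0 / params$K) / (1 - rho0 / params$K) *
      exp(-2 * (pi * params$sigma_rc / lambda)^2)
}

#' Dominant wavelength of the linear instability
#'
#' Maximizes `E(lambda)` over `lambda` in `(0, L/2]` by multi-start local
#' optimization over a log-spaced seed grid.  A non-positive maximum means
#' the homogeneous state is linearly stable (no colonies expected).
#'
#' @param phi Fixed trait value.
#' @param params A [sim_params()] object.
#' @param lambda_max Upper bound on the search (default `L / 2`).
#' @return List with `lambda_star`, `E_star`, `rho0`, and logical
#'   `unstable`; `lambda_star` is `NA` when stable.
#' @export
dominant_wavelength <- function(phi, params, lambda_max = params$L / 2) {
  rho0 <- homogeneous_equilibrium(params, phi)
  if (!is.finite(rho0)) {
    return(list(lambda_star = NA_real_, E_star = NA_real_, rho0 = NA_real_,
                unstable = FALSE, viable = FALSE))
  }
  lo <- max(params$sigma_m / 10, params$dx)
  seeds <- exp(seq(log(lo), log(lambda_max), length.out = 60))
  Ev <- growth_eigenvalue(seeds, phi, params, rho0)
  best <- list(lambda = seeds[which.max(Ev)], E = max(Ev))
  peaks <- which(diff(sign(diff(Ev))) < 0) + 1L
  cand <- unique(c(peaks, which.max(Ev)))
  for (i in cand) {
    lwr <- seeds[max(1L, i - 1L)]
    upr <- seeds[min(length(seeds), i + 1L)]
    if (upr > lwr) {
      op <- optimize(function(l) growth_eigenvalue(l, phi, params, rho0),
                     c(lwr, upr), maximum = TRUE, tol = 1e-10)
      if (op$objective > best$E) best <- list(lambda = op$maximum, E = op$objective)
    }
  }
  unstable <- best$E > 0
  list(lambda_star = if (unstable) best$lambda else NA_real_,
       E_star = best$E, rho0 = rho0, unstable = unstable, viable = TRUE)
}

#' Phase scan over the scales of competition and motility
#'
#' Recomputes the equilibrium and maximizes the growth eigenvalue for every
#' combination of `sigma_rc` and `sigma_m` (the latter is imposed by setting
#' `k_D = d * sigma_m^2 / 2`), at fixed trait `phi`.  The sign of `E_star`
#' traces the stability boundary of colony formation.
#'
#' @param sigma_rc_values,sigma_m_values Grids of scale values.
#' @param phi Fixed trait value.
#' @param params Baseline [sim_params()].
#' @return Data frame with `sigma_rc`, `sigma_m`, `rho0`, `E_star`,
#'   `lambda_star`, `unstable`.
#' @export
phase_scan <- function(sigma_rc_values, sigma_m_values, phi, params) {
  rows <- list()
  for (src in sigma_rc_values) {
    for (sm in sigma_m_values) {
      p <- params
      p$sigma_rc <- src
      p$k_D <- p$d * sm^2 / 2
      p$sigma_m <- sm
      dw <- dominant_wavelength(phi, p)
      rows[[length(rows) + 1L]] <- data.frame(
        sigma_rc = src, sigma_m = sm, rho0 = dw$rho0, E_star = dw$E_star,
        lambda_star = dw$lambda_star, unstable = isTRUE(dw$unstable))
    }
  }
  do.call(rbind, rows)
}

#' Numerically linearized growth rate of the mean-field dynamics
#'
#' Independent check of the closed-form eigenvalue: integrates the
#' deterministic nonlocal mean-field equation for the density (logistic-type
#' growth with kernel-smoothed benefit and competition plus diffusion) from
#' `rho0` plus a tiny sinusoidal perturbation, and measures the exponential
#' growth rate of that Fourier mode by explicit time stepping.
#'
#' @param lambda Perturbation wavelength; must divide the domain used.
#' @param phi Fixed trait value.
#' @param params A [sim_params()] object.
#' @param n_waves Number of wavelengths in the integration domain.
#' @param cells_per_wave Grid resolution.
#' @param t_end Integration time (generations).
#' @param dt_int Integration time step.
#' @return Measured growth rate (per generation).
#' @export
mean_field_growth_rate <- function(lambda, phi, params, n_waves = 8,
                                   cells_per_wave = 128, t_end = 0.5,
                                   dt_int = 5e-4) {
  L <- n_waves * lambda
  X <- n_waves * cells_per_wave
  dx <- L / X
  grid <- grid_spec(X, dx, 1L)
  ka <- gaussian_kernel(params$sigma_a, grid)$values
  krc <- gaussian_kernel(params$sigma_rc, grid)$values
  ka_hat <- fft(ka) * dx
  krc_hat <- fft(krc) * dx
  rho0 <- homogeneous_equilibrium(params, phi)
  x <- (0:(X - 1)) * dx
  eps0 <- 1e-6 * rho0
  rho <- rho0 + eps0 * sin(2 * pi * x / lambda)
  mode_amp <- function(r) {
    co <- fft(r)[n_waves + 1L]  # the k = n_waves mode carries the sine
    2 * Mod(co) / X
  }
  a0 <- mode_amp(rho)
  n_it <- ceiling(t_end / dt_int)
  for (it in seq_len(n_it)) {
    rho_hat <- fft(rho)
    Arho <- Re(fft(rho_hat * ka_hat, inverse = TRUE)) / X
    Drho <- Re(fft(rho_hat * krc_hat, inverse = TRUE)) / X
    growth <- params$g0 * rho *
      (1 - params$c * phi + params$b_max * phi * Arho /
         (params$b_max / params$b0 + phi * Arho)) *
      (1 - Drho / params$K) - params$d * rho
    lap <- (c(rho[-1], rho[1]) + c(rho[X], rho[-X]) - 2 * rho) / dx^2
    rho <- rho + dt_int * (growth + params$k_D * lap)
  }
  log(mode_amp(rho) / a0) / (n_it * dt_int)
}
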