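#' Simulation parameters
#'
#' Assembles the full parameter set of the model in the reduced units in
#' which the death rate `d`, the scale of altruism `sigma_a`, and the cost per
#' trait unit `c` all equal 1.  Defaults depend on the habitat dimension and
#' correspond to the standard 1D and 2D settings of the model.
#'
#' @param dim Habitat dimension (1 or 2); selects the default set.
#' @param d Death rate (1/time).
#' @param sigma_a Scale of altruism (length); 1 by unit convention.
#' @param c Reproductive deficit per unit trait; 1 by unit convention.
#' @param g0 Basal reproduction rate.
#' @param sigma_rc Scale of resource competition (length).
#' @param k_D Motility (diffusion) constant (length^2/time).
#' @param K Carrying-capacity factor (count/length^dim).
#' @param b0 Basal benefit slope of the public good.
#' @param b_max Maximal (saturated) benefit of the public good.
#' @param mu Mutation probability per reproduction event.
#' @param m Mean absolute effect size of mutations.
#' @param L Habitat side length.
#' @param dx Grid spacing.
#' @param dt Computational time step.
#' @param T Simulated duration in generations.
#' @param seed RNG seed.
#' @param trait_mode `"effective"` (traits may go negative; behavior uses
#'   `phiE = max(phi, 0)`; the 1D convention) or `"truncate"` (mutations are
#'   floored at 0; the 2D convention).
#' @return A validated list of class `sim_params`, including the derived
#'   scale of motility `sigma_m = sqrt(2 k_D / d)`.
#' @export
sim_params <- function(dim = 1L,
                       d = 1, sigma_a = 1, c = 1, g0 = 5, sigma_rc = 4,
                       k_D = if (dim == 1L) 3e-2 else 4e-2,
                       K = if (dim == 1L) 100 else 40,
                       b0 = if (dim == 1L) 0.5 else 1,
                       b_max = if (dim == 1L) 2 else 5,
                       mu = if (dim == 1L) 5e-4 else 1e-3,
                       m = 5e-3,
                       L = if (dim == 1L) 819.2 else 102.4,
                       dx = if (dim == 1L) 1 / 80 else 0.1,
                       dt = 0.08,
                       T = if (dim == 1L) 160000 else 8000,
                       seed = 1L,
                       trait_mode = if (dim == 1L) "effective" else "truncate") {
  dim <- as.integer(dim)
  p <- list(dim = dim, d = d, sigma_a = sigma_a, c = c, g0 = g0,
            sigma_rc = sigma_rc, k_D = k_D, K = K, b0 = b0, b_max = b_max,
            mu = mu, m = m, L = L, dx = dx, dt = dt, T = T,
            seed = as.integer(seed),
            trait_mode = match.arg(trait_mode, c("effective", "truncate")))
  validate_params(p)
}

validate_params <- function(p) {
  if (!p$dim %in% c(1L, 2L)) stop("dim must be 1 or 2")
  for (nm in c("d", "sigma_a", "g0", "sigma_rc", "k_D", "K", "b0", "b_max",
               "m", "L", "dx", "dt")) {
    if (p[[nm]] <= 0) stop(sprintf("parameter %s must be positive", nm))
  }
  if (p$c < 0) stop("c must be nonnegative")
  if (p$mu < 0 || p$mu > 1) stop("mu must lie in [0, 1]")
  if (p$T < 0) stop("T must be nonnegative")
  if (p$d * p$dt > 1) stop("d*dt exceeds 1: death probability is not a probability")
  if (p$g0 * p$dt > 1) {
    stop(sprintf("g0*dt = %.3g exceeds 1: reproduction probability is not a probability",
                 p$g0 * p$dt))
  }
  X <- round(p$L / p$dx)
  if (abs(X * p$dx - p$L) > 1e-9 * p$L) stop("L must be an integer multiple of dx")
  p$X <- as.integer(X)
  p$sigma_m <- sqrt(2 * p$k_D / p$d)
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> dim=%d  L=%g (X=%d, dx=%g)  dt=%g  T=%g  mode=%s\n",
    x$dim, x$L, x$X, x$dx, x$dt, x$T, x$trait_mode))
  cat(sprintf("  d=%g g0=%g c=%g K=%g b0=%g b_max=%g mu=%g m=%g\n",
              x$d, x$g0, x$c, x$K, x$b0, x$b_max, x$mu, x$m))
  cat(sprintf("  sigma_a=%g sigma_rc=%g k_D=%g (sigma_m=%.3f)  seed=%d\n",
              x$sigma_a, x$sigma_rc, x$k_D, x$sigma_m, x$seed))
  invisible(x)
}

#' Grid specification implied by a parameter set
#' @param params A [sim_params()] object.
#' @return A [grid_spec()].
#' @export
params_grid <- function(params) {
  grid_spec(params$X, params$dx, params$dim)
}

config_keys <- c("dim", "d", "sigma_a", "c", "g0", "sigma_rc", "k_D", "K",
                 "b0", "b_max", "mu", "m", "L", "dx", "dt", "T", "seed",
                 "trait_mode")

#' Read a run configuration file
#'
#' The configuration is a flat key-value (YAML) file whose keys are the model
#' symbols (`d`, `sigma_a`, `c`, `g0`, `sigma_rc`, `k_D`, `K`, `b0`, `b_max`,
#' `mu`, `m`) plus `L`, `dx`, `dt`, `dim`, `seed`, `trait_mode`, `T`.
#' Missing keys are filled with the defaults for the requested `dim`;
#' unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return A validated [sim_params()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  dim <- if (!is.null(raw$dim)) as.integer(raw$dim) else 1L
  do.call(sim_params, c(list(dim = dim), raw[setdiff(names(raw), "dim")]))
}

#' Write a run configuration file
#' @param params A [sim_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  yaml::write_yaml(params[config_keys], path)
  invisible(path)
}
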