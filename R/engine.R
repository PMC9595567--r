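#' Initial population of defectors
#'
#' Places `round((1 - d/g0) * K * L^dim)` individuals at uniformly random
#' cells; all traits equal `init_phi` (0 for the standard all-defector
#' start).  The count is the homogeneous steady-state abundance obtained by
#' solving `g = d` for a uniform defector population.
#'
#' @param params A [sim_params()] object.
#' @param init_phi Initial trait value for every individual (default 0).
#' @return A population state: data frame with columns `id`, `cell_x`
#'   (0-based), `cell_y` (2D only), `phi`.
#' @export
init_population <- function(params, init_phi = 0) {
  n <- round((1 - params$d / params$g0) * params$K * params$L^params$dim)
  if (n < 1) stop("parameters imply an initial population below 1 individual")
  X <- params$X
  st <- data.frame(id = seq_len(n),
                   cell_x = sample.int(X, n, replace = TRUE) - 1L)
  if (params$dim == 2L) st$cell_y <- sample.int(X, n, replace = TRUE) - 1L
  st$phi <- rep(as.numeric(init_phi), length.out = n)
  st
}

#' Reproduction rate
#'
#' `g = max(g0 * (1 - c*phiE + b_max*A/(b_max/b0 + A)) * (1 - D/K), 0)`,
#' where `phiE = max(phi, 0)` is the effective trait, `A` the local public
#' good and `D` the local density.  Vectorized over all arguments.
#'
#' @param phi Trait value(s).
#' @param A Public good at the individual's position (nonnegative).
#' @param D Local density at the individual's position (nonnegative).
#' @param params A [sim_params()] object.
#' @return Reproduction rate(s), clamped at 0.
#' @export
reproduction_rate <- function(phi, A, D, params) {
  phiE <- pmax(phi, 0)
  g <- params$g0 *
    (1 - params$c * phiE + params$b_max * A / (params$b_max / params$b0 + A)) *
    (1 - D / params$K)
  pmax(g, 0)
}

#' Mutate offspring traits
#'
#' With probability `1 - mu` the parent's trait is inherited unchanged;
#' otherwise a perturbation with exponentially distributed magnitude (mean
#' `m`) and random sign is added.  In `"truncate"` mode negative results are
#' floored at 0; in `"effective"` mode traits may become negative.
#'
#' @param phi_parent Parent trait value(s).
#' @param params A [sim_params()] object.
#' @return Offspring trait value(s); uses R's RNG.
#' @export
mutate_trait <- function(phi_parent, params) {
  n <- length(phi_parent)
  hit <- runif(n) < params$mu
  delta <- ifelse(hit,
                  stats::rexp(n, rate = 1 / params$m) * sign(runif(n) - 0.5),
                  0)
  child <- phi_parent + delta
  if (params$trait_mode == "truncate") child <- pmax(child, 0)
  child
}

#' Run the individual-based simulation
#'
#' Executes `T/dt` steps of the reproduction-death-motility scheme and
#' records (i) a time series of population size, mean trait, and the
#' cumulative Price forces (selection, drift, mutational bias), and (ii)
#' population snapshots at interval boundaries carrying interval-ancestor
#' tags for lineage analysis.
#'
#' @param params A [sim_params()] object.
#' @param T Duration in generations (defaults to `params$T`).
#' @param init_phi Trait value given to all initial individuals.
#' @param init_state Optional starting population (overrides
#'   [init_population()]); a data frame with `cell_x` (0-based), optional
#'   `cell_y`, and `phi`.
#' @param record_every Record the series every this many steps (default: 1
#'   for runs up to 2000 steps, else 25).
#' @param interval_length Lineage-tagging interval in generations (default
#'   80); snapshots are taken and ancestor tags reset at every boundary.
#'   Set to `NULL` to disable snapshots.
#' @param seed RNG seed (defaults to `params$seed`); drives both the R-side
#'   initialization and the C++ simulation stream.
#' @param newborn_death Should newborns be exposed to the same step's death
#'   draw (default `TRUE`, consistent with expected offspring
#'   `(1 + g dt)(1 - d dt)`)?
#' @return A list of class `sim_run` with elements `series` (data frame),
#'   `snapshots` (list of data frames with `cell_x`, `cell_y`, `phi`, `anc`,
#'   attribute `t`), `final`, `extinct`, `params`, `interval_length`.
#' @export
run_simulation <- function(params, T = params$T, init_phi = 0,
                           init_state = NULL, record_every = NULL,
                           interval_length = 80, seed = params$seed,
                           newborn_death = TRUE) {
  grid <- params_grid(params)
  n_steps <- as.integer(round(T / params$dt))
  if (is.null(record_every)) record_every <- if (n_steps <= 2000L) 1L else 25L

  keep_snaps <- !is.null(interval_length)
  interval_steps <- if (keep_snaps) {
    is_ <- interval_length / params$dt
    if (abs(is_ - round(is_)) > 1e-9) {
      stop("interval_length must be an integer number of time steps")
    }
    as.integer(round(is_))
  } else 0L

  set.seed(seed)
  if (is.null(init_state)) init_state <- init_population(params, init_phi)
  cells <- if (nrow(init_state)) state_linear_cells(init_state, grid) else integer(0)

  krc <- gaussian_kernel(params$sigma_rc, grid)$values
  ka <- gaussian_kernel(params$sigma_a, grid)$values

  res <- run_sim_cpp(params, krc, ka,
                     cells, as.numeric(init_state$phi),
                     seq_len(nrow(init_state)) - 1L,
                     n_steps, as.integer(record_every), interval_steps,
                     keep_snaps, as.numeric(seed), newborn_death)

  snaps <- lapply(res$snapshots, function(s) {
    st <- linear_to_state(s$cell, grid)
    st$phi <- s$phi
    st$anc <- s$anc + 1L  # 1-based index into the previous boundary roster
    attr(st, "t") <- s$t
    st
  })
  final <- linear_to_state(res$final$cell, grid)
  final$phi <- res$final$phi

  structure(list(series = as.data.frame(res$series),
                 snapshots = snaps,
                 final = final,
                 extinct = res$extinct,
                 params = params,
                 interval_length = if (keep_snaps) interval_length else NA_real_,
                 seed = seed),
            class = "sim_run")
}

linear_to_state <- function(cell, grid) {
  X <- grid$cells_per_side
  if (grid$dim == 1L) {
    data.frame(cell_x = as.integer(cell))
  } else {
    data.frame(cell_x = as.integer(cell %% X), cell_y = as.integer(cell %/% X))
  }
}

#' @export
print.sim_run <- function(x, ...) {
  s <- x$series
  cat(sprintf("<sim_run> dim=%d, %d recorded times, t in [%g, %g]%s\n",
              x$params$dim, nrow(s), min(s$t), max(s$t),
              if (x$extinct) " (EXTINCT)" else ""))
  cat(sprintf("  final n=%g, mean phi_E=%.4g; %d snapshots\n",
              s$n[nrow(s)], s$mean_phi_eff[nrow(s)], length(x$snapshots)))
  invisible(x)
}

#' Density and public-good fields of a population state
#'
#' Convenience wrapper computing `D` (bandwidth `sigma_rc`) and `A`
#' (bandwidth `sigma_a`, effective-trait weighted) exactly as the engine's
#' step 1 does.
#'
#' @param state Population state data frame.
#' @param params A [sim_params()] object.
#' @return List with `scalar_field`s `D` and `A`.
#' @export
compute_fields <- function(state, params) {
  grid <- params_grid(params)
  list(D = density_field(state, params$sigma_rc, grid),
       A = public_good_field(state, params$sigma_a, grid))
}
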