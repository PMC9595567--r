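#' Kernel-weighted trait of interaction partners
#'
#' For each individual, the effective traits of all *other* individuals
#' weighted by the altruism kernel:
#' `phi'_i = sum_{j != i} phiE_j G_a(x_i - x_j; sigma_a)`.  Computed as the
#' public-good field at the individual's cell minus its own contribution
#' (`phiE_i` times the discrete kernel value at zero offset).
#'
#' @param state Population state with `cell_x` (and `cell_y` in 2D) and `phi`.
#' @param params A [sim_params()] object.
#' @return Numeric vector `phi_prime`, one value per individual.
#' @export
neighbor_weighted_trait <- function(state, params) {
  grid <- params_grid(params)
  A <- public_good_field(state, params$sigma_a, grid)
  k0 <- gaussian_kernel(params$sigma_a, grid)$values[1]
  idx <- state_linear_cells(state, grid)
  A$values[idx + 1L] - pmax(state$phi, 0) * k0
}

#' Queller partial-regression partition of selection
#'
#' Least-squares fit `w = alpha + beta_direct * phi + beta_indirect * phi'`
#' splits the selection differential into a direct component
#' `S_direct = beta_direct * Var(phi)` (the cost of one's own altruism) and
#' an indirect component `S_indirect = beta_indirect * Cov(phi', phi)` (the
#' benefit received from altruistic neighbours); by the normal equations they
#' sum to `Cov(phi, w)`.  The Hamilton's-rule quantities are the cost
#' `c_H = -beta_direct`, benefit `b_H = beta_indirect`, and regression
#' relatedness `R = Cov(phi, phi') / Var(phi)`, which is unbounded above.
#'
#' @param phi Trait values.
#' @param phi_prime Kernel-weighted partner traits
#'   ([neighbor_weighted_trait()]).
#' @param w Relative fitness (expected or realized).
#' @return List with `S_direct`, `S_indirect`, `S_total`, `cost`, `benefit`,
#'   `relatedness`, and the raw coefficients.
#' @export
queller_partition <- function(phi, phi_prime, w) {
  v11 <- pcov(phi, phi)
  v22 <- pcov(phi_prime, phi_prime)
  v12 <- pcov(phi, phi_prime)
  if (v11 <= 0) stop("Var(phi) must be positive for the regression")
  det <- v11 * v22 - v12^2
  if (v22 > 0 && det / (v11 * v22) < 1e-12) {
    stop("phi and phi' are collinear; partition undefined")
  }
  c1 <- pcov(phi, w)
  c2 <- pcov(phi_prime, w)
  if (v22 == 0) {
    beta1 <- c1 / v11
    beta2 <- 0
  } else {
    beta1 <- (c1 * v22 - c2 * v12) / det
    beta2 <- (c2 * v11 - c1 * v12) / det
  }
  list(S_direct = beta1 * v11,
       S_indirect = beta2 * v12,
       S_total = c1,
       cost = -beta1,
       benefit = beta2,
       relatedness = v12 / v11,
       beta_direct = beta1, beta_indirect = beta2)
}

#' Inclusive-fitness time series of a run
#'
#' Applies [queller_partition()] at each lineage snapshot of a run.  By
#' default the per-step expected relative fitness
#' `E[W_i] / <E[W]>` (conditional on the local fields) is used, since the
#' realized single-step fitness is nearly degenerate; set
#' `fitness = "realized"` to use the interval descendant counts instead.
#'
#' @param run A `sim_run` with snapshots.
#' @param params A [sim_params()] object.
#' @param fitness `"expected"` (default) or `"realized"`.
#' @return Data frame with columns `t`, `S_direct`, `S_indirect`, `S_total`,
#'   `cost`, `benefit`, `relatedness`.
#' @export
hamilton_series <- function(run, params, fitness = c("expected", "realized")) {
  fitness <- match.arg(fitness)
  snaps <- run$snapshots
  n_snap <- length(snaps)
  idx <- if (fitness == "expected") seq_len(n_snap) else seq_len(n_snap - 1L)
  grid <- params_grid(params)
  rows <- lapply(idx, function(i) {
    st <- snaps[[i]]
    if (var(st$phi) <= 0) return(NULL)
    pp <- neighbor_weighted_trait(st, params)
    if (fitness == "expected") {
      fl <- compute_fields(st, params)
      ci <- state_linear_cells(st, grid) + 1L
      g <- reproduction_rate(st$phi, fl$A$values[ci], fl$D$values[ci], params)
      ew <- expected_offspring(g, params$d, params$dt)
      w <- ew / mean(ew)
    } else {
      fit <- interval_fitness(nrow(st), snaps[[i + 1L]]$anc)
      w <- fit$w
    }
    q <- queller_partition(st$phi, pp, w)
    data.frame(t = attr(st, "t"), S_direct = q$S_direct,
               S_indirect = q$S_indirect, S_total = q$S_total,
               cost = q$cost, benefit = q$benefit,
               relatedness = q$relatedness)
  })
  do.call(rbind, rows)
}
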