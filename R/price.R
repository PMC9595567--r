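#' Expected number of same-step offspring
#'
#' Expected count of an individual's surviving descendants (itself included)
#' after one computational time step, conditional on its current local
#' density and public good: `(1 + g*dt) * (1 - d*dt)`.
#'
#' @param g Reproduction rate(s).
#' @param d Death rate.
#' @param dt Time step.
#' @return Expected offspring number(s).
#' @export
expected_offspring <- function(g, d, dt) {
  pr <- g * dt
  pd <- d * dt
  if (any(pr < 0 | pr > 1) || any(pd < 0 | pd > 1)) {
    stop("g*dt and d*dt must lie in [0, 1]")
  }
  (1 + pr) * (1 - pd)
}

pcov <- function(x, y) mean(x * y) - mean(x) * mean(y)

#' Price decomposition of one step's trait change
#'
#' Splits the realized change in the population mean trait over one step into
#' natural selection, random drift, and transmission (mutation) bias.  With
#' `w_i = W_i / Wbar` the realized relative fitness and
#' `v_i = E[W_i] / <E[W]>` the conditional expected relative fitness (given
#' the local fields), selection is `Cov_i(phi_i, v_i)`, drift is
#' `Cov_i(phi_i, w_i) - selection`, and bias is the fitness-weighted mean
#' trait change between each parent and its surviving same-step descendants.
#' The three components sum to the realized change exactly (Price identity).
#'
#' @param record A step record: list/data frame with per-parent `phi`
#'   (trait), `ew` (expected offspring), `W` (realized surviving descendant
#'   count, self included), and `desc_sum` (summed trait of those
#'   descendants; equals `W * phi` when no mutation occurred).
#' @return A list with `selection`, `drift`, `bias`, `delta_mean`, and
#'   `terminal` (TRUE when the population went extinct during the step, in
#'   which case the components are `NA`).
#' @export
decompose_step <- function(record) {
  phi <- record$phi
  W <- record$W
  n_desc <- sum(W)
  if (n_desc == 0) {
    return(list(selection = NA_real_, drift = NA_real_, bias = NA_real_,
                delta_mean = NA_real_, terminal = TRUE))
  }
  v <- record$ew / mean(record$ew)
  selection <- pcov(phi, v)
  cov_w <- sum(phi * W) / n_desc - mean(phi)  # Cov(phi, W/Wbar); mean w = 1
  drift <- cov_w - selection
  bias <- sum(record$desc_sum) / n_desc - sum(phi * W) / n_desc
  list(selection = selection, drift = drift, bias = bias,
       delta_mean = selection + drift + bias, terminal = FALSE)
}

#' Accumulate per-step force decompositions
#'
#' @param decomps A list of [decompose_step()] results for contiguous steps.
#' @return Data frame with per-step components and running sums
#'   `cum_selection`, `cum_drift`, `cum_bias`; the cumulative columns sum to
#'   the cumulative realized trait change at every step.
#' @export
accumulate_forces <- function(decomps) {
  sel <- vapply(decomps, `[[`, numeric(1), "selection")
  dri <- vapply(decomps, `[[`, numeric(1), "drift")
  bia <- vapply(decomps, `[[`, numeric(1), "bias")
  dm <- vapply(decomps, `[[`, numeric(1), "delta_mean")
  data.frame(step = seq_along(decomps),
             selection = sel, drift = dri, bias = bia, delta_mean = dm,
             cum_selection = cumsum(sel), cum_drift = cumsum(dri),
             cum_bias = cumsum(bia), cum_delta = cumsum(dm))
}
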