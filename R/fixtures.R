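#' Deterministic analysis fixtures
#'
#' Hand-built 1D populations (no RNG) exercising every stage of the colony
#' tracking and multilevel-selection analysis without running simulations.
#' All fixtures live on a 256-cell grid with `dx = 0.1` (`L = 25.6`),
#' `K = 100`, and the default hysteresis thresholds `T_low = 20`,
#' `T_high = 70`.  The habitat is kept small so that the smoothed density is
#' strictly positive everywhere (no flat zero plateaus, which carry no
#' strict minima).
#'
#' Available fixtures:
#' \describe{
#'   \item{`two_clusters`}{Two tight clusters on opposite sides of the ring;
#'     the tracker reports exactly two colonies.}
#'   \item{`fission`}{One colony at t1 whose descendants form two clearly
#'     separated clusters at t2 (gap density below `T_low`): ancestor
#'     fitness `V = 2`.}
#'   \item{`extinction`}{Two colonies at t1, one of which leaves no
#'     descendants at t2: its `V = 0`.}
#'   \item{`shallow_dip`}{A single colony whose t2 state has an interior
#'     density minimum between `T_low` and `T_high`: the tentative border is
#'     rejected (hysteresis) and the colony survives whole, `V = 1`.}
#'   \item{`mls_hand`}{Ten individuals in two colonies with scripted
#'     descendant counts for hand-checkable Price/MLS arithmetic.}
#' }
#'
#' @param name Fixture name.
#' @return A list with `params`, `grid`, and either `state` (single
#'   snapshot) or `state1`/`state2` (a tracked interval; `state2` carries
#'   `anc`), plus fixture-specific ground truth fields.
#' @export
make_fixture <- function(name = c("two_clusters", "fission", "extinction",
                                  "shallow_dip", "mls_hand")) {
  name <- match.arg(name)
  params <- sim_params(dim = 1L, L = 25.6, dx = 0.1, T = 0)
  grid <- params_grid(params)
  cl <- function(center, n, width = 2) fixture_cluster(center, n, width, grid)
  mk_state <- function(cells, phi = 0) {
    data.frame(id = seq_along(cells), cell_x = cells,
               phi = rep(phi, length.out = length(cells)))
  }

  fx <- switch(name,
    two_clusters = {
      st <- mk_state(c(cl(6.4, 400), cl(19.2, 400)),
                     phi = c(rep(0.08, 400), rep(0.02, 400)))
      list(state = st, n_colonies = 2L)
    },
    fission = {
      s1 <- mk_state(cl(12.8, 400), phi = 0.05)
      cells2 <- c(cl(9.8, 300), cl(15.8, 300))  # gap density ~ 0 << T_low
      s2 <- mk_state(cells2, phi = 0.05)
      s2$anc <- c(seq_len(300), 301:400, seq_len(200))
      list(state1 = s1, state2 = s2, V_expected = 2L)
    },
    extinction = {
      s1 <- mk_state(c(cl(6.4, 400), cl(19.2, 400)),
                     phi = c(rep(0.01, 400), rep(0.08, 400)))
      s2 <- mk_state(cl(19.2, 500), phi = 0.08)  # first colony died out
      s2$anc <- 400L + ((seq_len(500) - 1L) %% 400L + 1L)
      list(state1 = s1, state2 = s2, extinct_Phi_t1 = 0.01)
    },
    shallow_dip = {
      s1 <- mk_state(cl(12.8, 600, width = 4), phi = 0.05)
      # two sub-blocks whose saddle density falls between T_low and T_high
      cells2 <- c(cl(11.2, 300), cl(14.4, 300))
      s2 <- mk_state(cells2, phi = 0.05)
      s2$anc <- seq_len(600)
      list(state1 = s1, state2 = s2, n_colonies_expected = 1L)
    },
    mls_hand = {
      cells1 <- as.integer(c(62, 63, 64, 65, 66, 190, 191, 192, 193, 194))
      phi1 <- c(0.10, 0.12, 0.08, 0.10, 0.10, 0.00, 0.02, 0.00, 0.01, 0.02)
      s1 <- mk_state(cells1, phi = phi1)
      # scripted descendant counts: W = (2,1,1,1,2, 0,1,0,1,1)
      anc <- c(1L, 1L, 2L, 3L, 4L, 5L, 5L, 7L, 9L, 10L)
      cells2 <- c(62L, 63L, 63L, 64L, 65L, 66L, 67L, 191L, 193L, 194L)
      s2 <- mk_state(cells2, phi = phi1[anc])
      s2$anc <- anc
      list(state1 = s1, state2 = s2,
           W_expected = c(2L, 1L, 1L, 1L, 2L, 0L, 1L, 0L, 1L, 1L),
           colony_t1 = rep(c(1L, 2L), each = 5L))
    })
  c(list(name = name, params = params, grid = grid), fx)
}

# Dense block of cells around `center` (length units): `n` individuals spread
# cyclically over `width` length units, giving a smoothed density ~ n/width.
fixture_cluster <- function(center, n, width, grid) {
  half <- round(width / 2 / grid$spacing)
  cells <- round(center / grid$spacing) + ((0:(n - 1)) %% (2L * half + 1L)) - half
  as.integer(cells %% grid$cells_per_side)
}

#' Synthetic oscillating-gap snapshot sequence
#'
#' A sequence of lineage-tagged snapshots in which one colony first splits
#' (gap density far below `T_low`) and the gap density subsequently
#' oscillates between roughly `0.15 K` and `0.6 K` -- below `T_high` but
#' above `T_low`.  Used to verify that hysteresis keeps the once-created
#' border in place instead of emitting fission/fusion chatter.
#'
#' @param n_oscillations Number of shallow/deep oscillation pairs after the
#'   initial split (default 3).
#' @return List with `params`, `grid`, and `snapshots` (each with `cell_x`,
#'   `phi`, `anc`).
#' @export
make_oscillating_trace <- function(n_oscillations = 3) {
  params <- sim_params(dim = 1L, L = 25.6, dx = 0.1, T = 0)
  grid <- params_grid(params)
  n_side <- 300L
  two_blobs <- function(sep) {
    cells <- c(fixture_cluster(12.8 - sep / 2 - 1, n_side, 2, grid),
               fixture_cluster(12.8 + sep / 2 + 1, n_side, 2, grid))
    data.frame(id = seq_along(cells), cell_x = cells,
               phi = rep(c(0.06, 0.04), each = n_side))
  }
  snaps <- list()
  st <- data.frame(id = seq_len(2L * n_side),
                   cell_x = fixture_cluster(12.8, 2L * n_side, 4, grid),
                   phi = rep(c(0.06, 0.04), each = n_side))
  st$anc <- seq_len(nrow(st))
  snaps[[1]] <- st
  seps <- c(4, rep(c(0.9, 1.7), n_oscillations))  # deep split, then shallow dips
  for (s in seps) {
    st <- two_blobs(s)
    st$anc <- seq_len(nrow(st))  # side k descends from side k (stable lineages)
    snaps[[length(snaps) + 1L]] <- st
  }
  for (i in seq_along(snaps)) attr(snaps[[i]], "t") <- (i - 1) * 80
  list(params = params, grid = grid, snapshots = snaps)
}
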