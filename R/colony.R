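#' Smoothed population density for colony detection
#'
#' A kernel density estimate of the population with Gaussian bandwidth
#' `sigma_a / 2` (half the scale of altruism), periodic.  Colony borders are
#' identified with deep local minima of this field.
#'
#' @param state 1D population state data frame.
#' @param grid A [grid_spec()].
#' @param bandwidth Kernel standard deviation (default 0.5, i.e. `sigma_a/2`
#'   in reduced units).
#' @return A `scalar_field` with units count/length.
#' @export
smooth_density <- function(state, grid, bandwidth = 0.5) {
  if (grid$dim != 1L) stop("colony detection is defined for 1D habitats only")
  density_field(state, bandwidth, grid)
}

#' Strict local minima of a periodic field
#'
#' Cells `x` with `rho[x] < rho[x+1]` and `rho[x] < rho[x-1]`, indices
#' modulo the grid size.  Plateaus (exact ties) yield no minimum.
#'
#' @param rho A `scalar_field` or numeric vector (1D, periodic).
#' @return Integer vector of 0-based cell indices.
#' @export
find_local_minima <- function(rho) {
  v <- field_values(rho)
  X <- length(v)
  left <- c(v[X], v[-X])
  right <- c(v[-1], v[1])
  which(v < left & v < right) - 1L
}

#' Tentative colony borders from density minima
#'
#' Keeps minima with density below `T_high` and places a border on the
#' half-integer position next to each: between `x` and `x+1` when the central
#' derivative `(rho[x+1] - rho[x-1]) / (2 dx)` is negative or zero, between
#' `x-1` and `x` when it is positive.
#'
#' @param rho Smoothed density (`scalar_field` or numeric vector).
#' @param minima 0-based minima cells from [find_local_minima()].
#' @param T_high Upper hysteresis threshold (density units), e.g. `0.7 * K`.
#' @return Data frame with columns `border` (half-integer cell coordinate in
#'   `[0, X)`), `min_cell`, `rho_min`, sorted by border position.
#' @export
place_tentative_borders <- function(rho, minima, T_high) {
  v <- field_values(rho)
  X <- length(v)
  keep <- minima[v[minima + 1L] < T_high]
  if (!length(keep)) {
    return(data.frame(border = numeric(0), min_cell = integer(0),
                      rho_min = numeric(0)))
  }
  der <- v[(keep + 1L) %% X + 1L] - v[(keep - 1L) %% X + 1L]
  border <- ifelse(der > 0, keep - 0.5, keep + 0.5) %% X
  df <- data.frame(border = border, min_cell = keep, rho_min = v[keep + 1L])
  # Two adjacent minima can nominate the same half-integer position; keep the
  # deeper one.
  df <- df[order(df$border, df$rho_min), ]
  df <- df[!duplicated(df$border), ]
  rownames(df) <- NULL
  df
}

#' Partition a 1D state into colonies given accepted borders
#'
#' Segments between consecutive borders (periodic) define the colonies; every
#' individual belongs to exactly one colony.  With no borders the whole
#' habitat is a single colony.  Segments containing no individuals are merged
#' into a neighbour by discarding their shallower border.
#'
#' @param state Population state (1D) with `cell_x` and `phi`.
#' @param grid A [grid_spec()].
#' @param borders Data frame from [place_tentative_borders()].
#' @return A `colony_partition`: list with `borders` (data frame),
#'   `membership` (colony index per individual), and `colonies` (data frame
#'   `id`, `n`, `Phi`, `com` with the centre of mass in cell coordinates).
#' @export
partition_colonies <- function(state, grid, borders) {
  X <- grid$cells_per_side
  cells <- state$cell_x
  repeat {
    m <- nrow(borders)
    if (m == 0L) {
      membership <- rep(1L, length(cells))
      break
    }
    bpos <- borders$border
    idx <- findInterval(cells, bpos)
    membership <- ifelse(idx == 0L, m, idx)
    counts <- tabulate(membership, nbins = m)
    if (all(counts > 0L) || length(cells) == 0L) break
    # merge each empty segment into a neighbour: drop its shallower border
    empty <- which(counts == 0L)[1]
    b_start <- empty
    b_end <- if (empty == m) 1L else empty + 1L
    drop <- if (borders$rho_min[b_start] >= borders$rho_min[b_end]) b_start else b_end
    borders <- borders[-drop, , drop = FALSE]
  }
  m <- max(1L, nrow(borders))
  stats <- lapply(seq_len(m), function(j) {
    sel <- membership == j
    n_j <- sum(sel)
    if (n_j == 0L) return(data.frame(id = j, n = 0L, Phi = NA_real_, com = NA_real_))
    ph <- state$phi[sel]
    cj <- cells[sel]
    if (nrow(borders) == 0L) {
      ang <- cj / X * 2 * pi
      com <- (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi) * X) %% X
    } else {
      start <- borders$border[j]
      com <- (start + mean((cj - start) %% X)) %% X
    }
    data.frame(id = j, n = n_j, Phi = mean(ph), com = com)
  })
  structure(list(borders = borders,
                 membership = as.integer(membership),
                 colonies = do.call(rbind, stats)),
            class = "colony_partition")
}

#' @export
print.colony_partition <- function(x, ...) {
  cat(sprintf("<colony_partition> %d colonies, %d borders, N=%d\n",
              nrow(x$colonies), nrow(x$borders), length(x$membership)))
  invisible(x)
}

#' Assign an ancestor colony to each tentative colony
#'
#' Each colony at the end of an interval is mapped to the colony at the start
#' of the interval that contains the plurality of its members' individual
#' ancestors.  Ties go to the larger ancestral colony, then to the lower
#' colony index.
#'
#' @param membership_t2 Tentative colony index per t2 individual.
#' @param n_colonies_t2 Number of tentative t2 colonies.
#' @param anc Per-t2-individual 1-based index of its ancestor in the t1
#'   roster.
#' @param partition_t1 The finalized `colony_partition` at t1.
#' @return Integer vector: ancestor colony id for each t2 colony.
#' @export
assign_ancestors <- function(membership_t2, n_colonies_t2, anc, partition_t1) {
  anc_col <- partition_t1$membership[anc]
  sizes_t1 <- partition_t1$colonies$n
  vapply(seq_len(n_colonies_t2), function(j) {
    tab <- table(anc_col[membership_t2 == j])
    if (!length(tab)) return(NA_integer_)
    cand <- as.integer(names(tab)[tab == max(tab)])
    if (length(cand) > 1L) {
      cand <- cand[order(-sizes_t1[cand], cand)]
    }
    cand[1L]
  }, integer(1))
}

#' Finalize borders by hysteresis and tabulate colony events
#'
#' A tentative border whose two flanking tentative colonies share the same
#' ancestor reflects a possible incomplete division: it is kept only if the
#' density at its minimum is below `T_low`.  All other tentative borders are
#' accepted.  The surviving borders define the final t2 colonies; each
#' ancestral colony's fitness `V` is its number of offspring colonies
#' (`V = 0`: extinct; `V = 1`: survived; `V >= 2`: fission).
#'
#' @param state_t2 t2 population state with `cell_x`, `phi`, `anc`.
#' @param grid A [grid_spec()].
#' @param rho_t2 Smoothed density at t2.
#' @param tentative Tentative borders ([place_tentative_borders()]).
#' @param partition_t1 Finalized `colony_partition` at t1.
#' @param T_low Lower hysteresis threshold (e.g. `0.2 * K`).
#' @return List with the final `partition` (including `$ancestor` per t2
#'   colony) and `events` (data frame per t1 colony: `colony`, `n`, `Phi`,
#'   `V`, `label`, `offspring_Phi`).
#' @export
finalize_borders <- function(state_t2, grid, rho_t2, tentative, partition_t1,
                             T_low) {
  tent_part <- partition_colonies(state_t2, grid, tentative)
  m <- nrow(tent_part$colonies)
  anc_tent <- assign_ancestors(tent_part$membership, m, state_t2$anc, partition_t1)
  borders <- tent_part$borders
  if (nrow(borders) > 0L && m > 1L) {
    left <- c(m, seq_len(m - 1L))  # border j separates colony left[j] and j
    same_anc <- anc_tent[left] == anc_tent[seq_len(m)]
    reject <- same_anc & borders$rho_min >= T_low
    borders <- borders[!reject, , drop = FALSE]
  }
  partition <- partition_colonies(state_t2, grid, borders)
  n_fin <- nrow(partition$colonies)
  anc_fin <- assign_ancestors(partition$membership, n_fin, state_t2$anc, partition_t1)
  partition$ancestor <- anc_fin

  t1_cols <- partition_t1$colonies
  V <- tabulate(anc_fin, nbins = nrow(t1_cols))
  off_Phi <- vapply(seq_len(nrow(t1_cols)), function(j) {
    sel <- which(anc_fin == j)
    if (!length(sel)) NA_real_ else mean(partition$colonies$Phi[sel])
  }, numeric(1))
  events <- data.frame(
    colony = t1_cols$id, n = t1_cols$n, Phi = t1_cols$Phi, V = V,
    label = c("extinct", "survived", "fission")[pmin(V, 2L) + 1L],
    offspring_Phi = off_Phi)
  list(partition = partition, events = events)
}

#' Track colonies across all interval boundaries of a run
#'
#' Applies the detection/tracking procedure to consecutive lineage-tagged
#' snapshots: the first boundary is partitioned by accepting every density
#' minimum below `T_high`; each subsequent boundary is partitioned
#' tentatively, ancestors are assigned by individual lineage plurality, and
#' same-ancestor borders above `T_low` are rejected (hysteresis).
#'
#' @param run A `sim_run` (with snapshots), or a list of snapshot data
#'   frames with columns `cell_x`, `phi`, `anc`.
#' @param params A [sim_params()] object (supplies `K` and the grid).
#' @param T_low,T_high Hysteresis thresholds; defaults `0.2*K` and `0.7*K`.
#' @param bandwidth Smoothing bandwidth (default `sigma_a / 2`).
#' @return List of class `colony_tracking` with `partitions` (one per
#'   boundary), `events` (one data frame per interval), and `table`
#'   (combined per-colony per-boundary rows).
#' @export
track_colonies <- function(run, params, T_low = 0.2 * params$K,
                           T_high = 0.7 * params$K,
                           bandwidth = params$sigma_a / 2) {
  snaps <- if (inherits(run, "sim_run")) run$snapshots else run
  if (length(snaps) < 1L) stop("no snapshots to track")
  grid <- params_grid(params)

  partitions <- vector("list", length(snaps))
  events <- vector("list", max(0L, length(snaps) - 1L))

  rho <- smooth_density(snaps[[1]], grid, bandwidth)
  tb <- place_tentative_borders(rho, find_local_minima(rho), T_high)
  partitions[[1]] <- partition_colonies(snaps[[1]], grid, tb)
  partitions[[1]]$ancestor <- rep(NA_integer_, nrow(partitions[[1]]$colonies))

  if (length(snaps) > 1L) {
    for (i in seq(2L, length(snaps))) {
      st <- snaps[[i]]
      rho <- smooth_density(st, grid, bandwidth)
      tb <- place_tentative_borders(rho, find_local_minima(rho), T_high)
      fin <- finalize_borders(st, grid, rho, tb, partitions[[i - 1L]], T_low)
      partitions[[i]] <- fin$partition
      events[[i - 1L]] <- fin$events
    }
  }

  rows <- lapply(seq_along(partitions), function(i) {
    co <- partitions[[i]]$colonies
    data.frame(boundary = i - 1L,
               t = if (!is.null(attr(snaps[[i]], "t"))) attr(snaps[[i]], "t") else NA_real_,
               colony = co$id,
               ancestor = partitions[[i]]$ancestor,
               n = co$n, Phi = co$Phi, com = co$com)
  })
  structure(list(partitions = partitions, events = events,
                 table = do.call(rbind, rows)),
            class = "colony_tracking")
}

#' Write the colony lineage table
#' @param tracking A `colony_tracking` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(tracking, path) {
  write.table(tracking$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
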