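#' Interval fitness from lineage tags
#'
#' Absolute fitness `W_i` of each individual alive at the interval start is
#' its number of descendants (itself included, through survival) at the
#' interval end, obtained from the inherited ancestor tags; relative fitness
#' is `w_i = W_i / Wbar`.
#'
#' @param n_t1 Number of individuals at the interval start.
#' @param anc_t2 Per-t2-individual 1-based ancestor index into the t1 roster.
#' @return List with `W`, `w` and `Wbar`; `w` is `NA` if the population went
#'   extinct during the interval.
#' @export
interval_fitness <- function(n_t1, anc_t2) {
  if (n_t1 < 1L) stop("empty population at interval start")
  W <- tabulate(anc_t2, nbins = n_t1)
  Wbar <- mean(W)
  list(W = W, w = if (Wbar > 0) W / Wbar else rep(NA_real_, n_t1), Wbar = Wbar)
}

#' MLS 1: within- and among-colony components of selection
#'
#' The individual-level selection differential `S = Cov_i(phi_i, w_i)` is
#' split by the law of total covariance: `S_among` is the size-weighted
#' covariance of colony mean trait and colony mean relative fitness, and
#' `S_within` is the size-weighted mean of the within-colony covariances.
#' Covariances use population (1/N) normalization.
#'
#' @param phi Trait values of the t1 individuals.
#' @param w Relative fitness of the t1 individuals.
#' @param colony Colony index per t1 individual (1-based, no empty classes).
#' @return List with `S`, `S_within`, `S_among`, and the per-colony table.
#' @export
mls1_decompose <- function(phi, w, colony) {
  N <- length(phi)
  if (length(w) != N || length(colony) != N) stop("inputs differ in length")
  m <- max(colony)
  n_j <- tabulate(colony, nbins = m)
  if (any(n_j == 0L)) stop("colony assignment contains an empty colony")
  S <- pcov(phi, w)
  grp <- factor(colony, levels = seq_len(m))
  Phi_j <- rowsum(phi, grp)[, 1L] / n_j
  w_j <- rowsum(w, grp)[, 1L] / n_j
  pw_j <- rowsum(phi * w, grp)[, 1L] / n_j
  f <- n_j / N
  S_among <- sum(f * Phi_j * w_j) - sum(f * Phi_j) * sum(f * w_j)
  S_within <- sum(f * (pw_j - Phi_j * w_j))
  list(S = S, S_within = S_within, S_among = S_among,
       colonies = data.frame(colony = seq_len(m), n = n_j, Phi = Phi_j,
                             w_mean = w_j))
}

#' MLS 2: colony-level selection and transmission
#'
#' Applies the Price equation to the population of colonies: colony fitness
#' `V_j` is the number of offspring colonies at the interval end.  With
#' `Vbar` the mean fitness over t1 colonies,
#' `S_col = Cov_j(Phi_j, V_j) / Vbar` and
#' `T_col = (1 / (N_c Vbar)) * sum_j V_j (offspring_Phi_j - Phi_j)`; the two
#' sum to the change in the unweighted colony-mean trait.
#'
#' @param events Per-t1-colony data frame with `Phi`, `V`, `offspring_Phi`
#'   (as produced by [finalize_borders()] / [track_colonies()]).
#' @return List with `S_col`, `T_col`, `delta_Phi` (their sum), and `Vbar`;
#'   all `NA` when every colony went extinct.
#' @export
mls2_decompose <- function(events) {
  V <- events$V
  Phi <- events$Phi
  Vbar <- mean(V)
  if (Vbar == 0) {
    return(list(S_col = NA_real_, T_col = NA_real_, delta_Phi = NA_real_,
                Vbar = 0))
  }
  S_col <- pcov(Phi, V) / Vbar
  dPhi <- ifelse(V > 0, events$offspring_Phi - Phi, 0)
  T_col <- sum(V * dPhi) / (length(V) * Vbar)
  list(S_col = S_col, T_col = T_col, delta_Phi = S_col + T_col, Vbar = Vbar)
}

#' Split colony-level selection into death and birth components
#'
#' Writes `V_j = s_j + b_j` with survival indicator `s_j = 1{V_j >= 1}` and
#' extra births `b_j = V_j - s_j`; by linearity of the covariance,
#' `S_col_death = Cov_j(Phi_j, s_j)/Vbar` and
#' `S_col_birth = Cov_j(Phi_j, b_j)/Vbar` sum exactly to `S_col`.
#'
#' @inheritParams mls2_decompose
#' @return List with `S_col_death` and `S_col_birth` (`NA` on total
#'   extinction).
#' @export
split_colony_selection <- function(events) {
  V <- events$V
  Vbar <- mean(V)
  if (Vbar == 0) return(list(S_col_death = NA_real_, S_col_birth = NA_real_))
  s <- as.numeric(V >= 1)
  b <- V - s
  list(S_col_death = pcov(events$Phi, s) / Vbar,
       S_col_birth = pcov(events$Phi, b) / Vbar)
}

#' Block-averaged standard error of the mean
#'
#' For an autocorrelated series, block means over blocks of doubling length
#' are used to estimate the standard error of the mean; the reported SEM is
#' the plateau value, the first block length at which doubling the blocks
#' changes the estimate by less than 10%.
#'
#' @param series Numeric series (length >= 4 for blocking; shorter series
#'   fall back to the naive SEM with a warning).
#' @param l_max Largest block length considered (default `length/4`).
#' @return List with `mean`, `sem`, `ci` (mean +/- 2 SEM), `block_length`,
#'   and the per-length table `sems`.
#' @export
block_sem <- function(series, l_max = floor(length(series) / 4)) {
  n <- length(series)
  mu <- mean(series)
  if (n < 4L || l_max < 2L) {
    warning("series too short for block averaging; returning naive SEM")
    sem <- sd(series) / sqrt(n)
    return(list(mean = mu, sem = sem, ci = mu + c(-2, 2) * sem,
                block_length = 1L, sems = NULL))
  }
  ls <- 2^(0:floor(log2(l_max)))
  sems <- vapply(ls, function(l) {
    nb <- floor(n / l)
    bm <- colMeans(matrix(series[seq_len(nb * l)], nrow = l))
    sd(bm) / sqrt(nb)
  }, numeric(1))
  sem <- sems[length(sems)]
  blk <- ls[length(ls)]
  for (i in seq_len(length(ls) - 1L)) {
    if (sems[i] == 0 || abs(sems[i + 1L] - sems[i]) / sems[i] < 0.1) {
      sem <- sems[i + 1L]
      blk <- ls[i + 1L]
      break
    }
  }
  list(mean = mu, sem = sem, ci = mu + c(-2, 2) * sem, block_length = blk,
       sems = data.frame(l = ls, sem = sems))
}

#' Per-interval multilevel-selection accounting of a run
#'
#' For every 80-generation interval between lineage-tagged snapshots this
#' computes the realized change in mean trait, the individual-level selection
#' differential with its MLS 1 within/among split, and the MLS 2 colony-level
#' selection and transmission terms with the death/birth split of colony
#' selection.
#'
#' @param run A `sim_run` with snapshots.
#' @param params A [sim_params()] object.
#' @param tracking Optional precomputed [track_colonies()] result.
#' @param ... Passed to [track_colonies()].
#' @return Data frame of class `mls_intervals`, one row per interval, with
#'   columns `interval`, `t1`, `t2`, `delta_mean`, `S`, `S_within`,
#'   `S_among`, `delta_Phi`, `S_col`, `T_col`, `S_col_death`, `S_col_birth`,
#'   `n_colonies`; the tracking object is attached as an attribute.
#' @export
mls_intervals <- function(run, params, tracking = NULL, ...) {
  snaps <- run$snapshots
  if (length(snaps) < 2L) stop("need at least two snapshots (one interval)")
  if (is.null(tracking)) tracking <- track_colonies(run, params, ...)
  out <- lapply(seq_len(length(snaps) - 1L), function(i) {
    s1 <- snaps[[i]]
    s2 <- snaps[[i + 1L]]
    part1 <- tracking$partitions[[i]]
    ev <- tracking$events[[i]]
    fit <- interval_fitness(nrow(s1), s2$anc)
    m1 <- mls1_decompose(s1$phi, fit$w, part1$membership)
    m2 <- mls2_decompose(ev)
    sp <- split_colony_selection(ev)
    data.frame(interval = i,
               t1 = attr(s1, "t"), t2 = attr(s2, "t"),
               delta_mean = mean(s2$phi) - mean(s1$phi),
               S = m1$S, S_within = m1$S_within, S_among = m1$S_among,
               delta_Phi = m2$delta_Phi, S_col = m2$S_col, T_col = m2$T_col,
               S_col_death = sp$S_col_death, S_col_birth = sp$S_col_birth,
               n_colonies = nrow(part1$colonies))
  })
  res <- do.call(rbind, out)
  attr(res, "tracking") <- tracking
  class(res) <- c("mls_intervals", class(res))
  res
}

#' Summary statistics of an interval analysis
#'
#' Sign fractions and block-SEM 95% confidence intervals for each component,
#' over a chosen tail of the interval series (steady-state window).
#'
#' @param intervals An [mls_intervals()] data frame.
#' @param last_fraction Fraction of intervals (from the end) to summarize
#'   (default 0.5, the steady-state convention).
#' @return Data frame with one row per component: mean, SEM, CI bounds, and
#'   fractions of intervals positive/negative/zero.
#' @export
mls_summary <- function(intervals, last_fraction = 0.5) {
  n <- nrow(intervals)
  keep <- intervals[seq.int(max(1L, n - floor(last_fraction * n) + 1L), n), ]
  comps <- c("delta_mean", "S", "S_within", "S_among", "delta_Phi",
             "S_col", "T_col", "S_col_death", "S_col_birth")
  do.call(rbind, lapply(comps, function(cmp) {
    x <- keep[[cmp]]
    x <- x[is.finite(x)]
    bs <- if (length(x) >= 8) {
      block_sem(x)
    } else if (length(x) >= 2) {
      s <- sd(x) / sqrt(length(x))
      list(mean = mean(x), sem = s, ci = mean(x) + c(-2, 2) * s)
    } else {
      list(mean = mean(x), sem = NA_real_, ci = c(NA_real_, NA_real_))
    }
    data.frame(component = cmp, mean = bs$mean, sem = bs$sem,
               ci_lo = bs$ci[1], ci_hi = bs$ci[2],
               frac_pos = mean(x > 0), frac_neg = mean(x < 0),
               frac_zero = mean(x == 0), n = length(x))
  }))
}
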