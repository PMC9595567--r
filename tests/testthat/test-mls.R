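test_that("interval fitness counts descendants through lineage tags", {
  # no births or deaths: everyone their own single descendant
  f <- interval_fitness(5, 1:5)
  expect_equal(f$W, rep(1L, 5))
  expect_equal(f$w, rep(1, 5))

  # 3 individuals: one dies, one doubles -> W = (0, 2, 1)
  f2 <- interval_fitness(3, c(2L, 2L, 3L))
  expect_equal(f2$W, c(0L, 2L, 1L))
  expect_equal(f2$w, c(0, 2, 1))
  expect_equal(sum(f2$W), 3)  # conservation: sums to t2 population size

  fx <- make_fixture("mls_hand")
  f3 <- interval_fitness(nrow(fx$state1), fx$state2$anc)
  expect_equal(f3$W, fx$W_expected)
  expect_equal(sum(f3$W), nrow(fx$state2))

  expect_error(interval_fitness(0, integer(0)), "empty")
})

test_that("MLS 1 splits selection exactly into within and among components", {
  # single colony: everything is within-colony selection
  set.seed(41)
  phi <- rnorm(12, 0.05, 0.02)
  w <- rpois(12, 2) / 2
  m1 <- mls1_decompose(phi, w, rep(1L, 12))
  expect_lt(abs(m1$S_among), 1e-15)
  expect_lt(abs(m1$S_within - m1$S), 1e-12)

  # internally uniform colonies: everything is among-colony selection
  phi2 <- rep(c(0.1, 0.02, 0.06), times = c(4, 5, 3))
  w2 <- rep(c(1.5, 0.5, 1.0), times = c(4, 5, 3))
  col2 <- rep(1:3, times = c(4, 5, 3))
  m2 <- mls1_decompose(phi2, w2, col2)
  expect_equal(m2$S_within, 0, tolerance = 1e-15)
  expect_equal(m2$S_among, m2$S, tolerance = 1e-15)

  # random fixtures vs a brute-force total-covariance oracle
  set.seed(42)
  for (rep in 1:10) {
    n <- 20
    phi <- rnorm(n, 0.05, 0.03)
    w <- rpois(n, 1.5) / 1.5
    col <- sample(1:3, n, replace = TRUE)
    col <- as.integer(factor(col))  # make sure no empty colony
    m <- mls1_decompose(phi, w, col)
    expect_equal(m$S, pop_cov(phi, w), tolerance = 1e-12)
    S_among_brute <- {
      f <- tabulate(col) / n
      Phi <- tapply(phi, col, mean)
      wj <- tapply(w, col, mean)
      sum(f * (Phi - sum(f * Phi)) * (wj - sum(f * wj)))
    }
    expect_equal(m$S_among, S_among_brute, tolerance = 1e-12)
    expect_equal(m$S_within + m$S_among, m$S, tolerance = 1e-12)
  }
  expect_error(mls1_decompose(phi, w, c(rep(1L, 19), 3L)), "empty")
})

test_that("MLS 2 colony-level selection and transmission behave as derived", {
  # all colonies survive without reproducing: no colony selection,
  # transmission is the mean within-colony change
  ev <- data.frame(Phi = c(0.1, 0.05, 0.0), V = c(1L, 1L, 1L),
                   offspring_Phi = c(0.08, 0.05, 0.01))
  m <- mls2_decompose(ev)
  expect_equal(m$S_col, 0, tolerance = 1e-15)
  expect_equal(m$T_col, mean(c(-0.02, 0, 0.01)), tolerance = 1e-15)

  # equal colony traits: no selection regardless of fitness differences
  ev2 <- data.frame(Phi = rep(0.05, 3), V = c(2L, 0L, 1L),
                    offspring_Phi = c(0.05, NA, 0.05))
  expect_equal(mls2_decompose(ev2)$S_col, 0, tolerance = 1e-15)

  # 2 colonies, Phi = (0.1, 0), V = (2, 0), offspring faithful:
  # Vbar = 1, S_col = Cov(Phi, V) = 0.05, T_col = 0
  ev3 <- data.frame(Phi = c(0.1, 0), V = c(2L, 0L), offspring_Phi = c(0.1, NA))
  m3 <- mls2_decompose(ev3)
  expect_equal(m3$S_col, 0.05, tolerance = 1e-15)
  expect_equal(m3$T_col, 0)

  # all extinct: flagged undefined
  ev4 <- data.frame(Phi = c(0.1, 0), V = c(0L, 0L), offspring_Phi = c(NA, NA))
  expect_true(is.na(mls2_decompose(ev4)$S_col))
})

test_that("the death/birth split of colony selection is exact and sparse", {
  # no extinctions: survival indicator is constant -> death component zero
  ev <- data.frame(Phi = c(0.1, 0.02, 0.05), V = c(2L, 1L, 1L),
                   offspring_Phi = c(0.1, 0.02, 0.05))
  sp <- split_colony_selection(ev)
  expect_equal(sp$S_col_death, 0, tolerance = 1e-15)
  expect_equal(sp$S_col_death + sp$S_col_birth, mls2_decompose(ev)$S_col,
               tolerance = 1e-15)

  # no fissions: birth component zero
  ev2 <- data.frame(Phi = c(0.1, 0.02, 0.05), V = c(1L, 0L, 1L),
                    offspring_Phi = c(0.1, NA, 0.05))
  sp2 <- split_colony_selection(ev2)
  expect_equal(sp2$S_col_birth, 0, tolerance = 1e-15)

  # mixed case: components sum to S_col
  set.seed(44)
  for (rep in 1:10) {
    ev3 <- data.frame(Phi = runif(6, 0, 0.1), V = rpois(6, 1),
                      offspring_Phi = runif(6, 0, 0.1))
    if (mean(ev3$V) == 0) ev3$V[1] <- 1L
    sp3 <- split_colony_selection(ev3)
    expect_equal(sp3$S_col_death + sp3$S_col_birth,
                 mls2_decompose(ev3)$S_col, tolerance = 1e-12)
  }
})

test_that("block averaging recovers the SEM inflation of autocorrelated series", {
  # constant series
  bs0 <- block_sem(rep(2.5, 64))
  expect_equal(bs0$sem, 0)
  expect_equal(bs0$mean, 2.5)

  # iid series: plateau close to the naive SEM
  set.seed(45)
  x <- rnorm(4096)
  bs <- block_sem(x)
  naive <- sd(x) / sqrt(length(x))
  expect_equal(bs$sem, naive, tolerance = 0.25)

  # AR(1) with rho = 0.8: inflation ~ sqrt((1+rho)/(1-rho)) = 3
  set.seed(46)
  n <- 4096
  rho <- 0.8
  ar <- numeric(n)
  for (i in 2:n) ar[i] <- rho * ar[i - 1] + rnorm(1)
  bsa <- block_sem(ar)
  naive_ar <- sd(ar) / sqrt(n)
  inflation <- bsa$sem / naive_ar
  expect_equal(inflation, sqrt((1 + rho) / (1 - rho)), tolerance = 0.2)
  expect_gt(bsa$sem, naive_ar)

  expect_warning(block_sem(c(1, 2)), "short")
})

test_that("hand-built interval reproduces direct Price/MLS arithmetic", {
  fx <- make_fixture("mls_hand")
  fit <- interval_fitness(nrow(fx$state1), fx$state2$anc)
  phi <- fx$state1$phi
  m1 <- mls1_decompose(phi, fit$w, fx$colony_t1)
  expect_equal(m1$S, pop_cov(phi, fit$w), tolerance = 1e-15)
  expect_equal(m1$S_within + m1$S_among, m1$S, tolerance = 1e-14)

  # the tracker should find the same two colonies and the same split
  tr <- track_colonies(list(fx$state1, fx$state2), fx$params)
  expect_equal(nrow(tr$partitions[[1]]$colonies), 2L)
  grp <- tr$partitions[[1]]$membership
  expect_equal(length(unique(paste(grp, fx$colony_t1))), 2L)  # same grouping
})

test_that("interval accounting on a simulated run satisfies every identity", {
  r <- identity_run_altruist()
  p <- identity_params()
  iv <- mls_intervals(r, p)
  expect_gte(nrow(iv), 4)
  ok <- is.finite(iv$S_col)
  expect_lt(max(abs(iv$S_within + iv$S_among - iv$S)), 1e-12)
  expect_lt(max(abs(iv$S_col_death[ok] + iv$S_col_birth[ok] - iv$S_col[ok])),
            1e-12)
  # MLS 2 identity against independently recomputed colony means
  tr <- attr(iv, "tracking")
  for (i in which(ok)) {
    dPhi <- mean(tr$partitions[[i + 1]]$colonies$Phi) -
      mean(tr$partitions[[i]]$colonies$Phi)
    expect_lt(abs(iv$S_col[i] + iv$T_col[i] - dPhi), 1e-12)
  }
  # individual-level S equals the covariance recomputed from scratch
  s1 <- r$snapshots[[1]]; s2 <- r$snapshots[[2]]
  fit <- interval_fitness(nrow(s1), s2$anc)
  expect_equal(iv$S[1], pop_cov(s1$phi, fit$w), tolerance = 1e-14)
  expect_equal(iv$delta_mean[1], mean(s2$phi) - mean(s1$phi), tolerance = 1e-14)

  sm <- mls_summary(iv)
  expect_true(all(c("S_within", "S_col_death") %in% sm$component))
  expect_true(all(abs(sm$frac_pos + sm$frac_neg + sm$frac_zero - 1) < 1e-12))
})

test_that("quasi-steady state: mean within-colony selection is negative, rescued among colonies", {
  iv <- steady_mls()
  post <- iv[iv$t1 >= 8000, ]
  ci <- function(cmp) {
    x <- post[[cmp]]
    block_sem(x[is.finite(x)])$ci
  }
  # 95% block-SEM confidence intervals exclude zero, with the signs of the
  # within-colony tragedy of the commons and its colony-level rescue
  expect_lt(ci("S_within")[2], 0)
  expect_gt(ci("S_among")[1], 0)
  expect_gt(ci("S_col")[1], 0)
  expect_lt(ci("T_col")[2], 0)
  # colony-level selection acts through both fewer deaths and more fissions,
  # with the death component the larger of the two
  expect_gt(ci("S_col_death")[1], 0)
  expect_gt(ci("S_col_birth")[1], 0)
  d <- post$S_col_death[is.finite(post$S_col_death)]
  b <- post$S_col_birth[is.finite(post$S_col_birth)]
  expect_gt(mean(d), mean(b))
})
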