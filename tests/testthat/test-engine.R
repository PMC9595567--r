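test_that("initial defector population matches the carrying-capacity count", {
  p1 <- sim_params(dim = 1)
  set.seed(1)
  st1 <- init_population(p1)
  expect_equal(nrow(st1), 65536L)  # (1 - d/g0) * K * L = 0.8 * 100 * 819.2
  expect_true(all(st1$phi == 0))
  expect_true(all(st1$cell_x >= 0 & st1$cell_x < p1$X))
  expect_equal(anyDuplicated(st1$id), 0L)

  p2 <- sim_params(dim = 2)
  st2 <- init_population(p2)
  expect_equal(nrow(st2), round(0.8 * 40 * 102.4^2))  # 335 544
  expect_true(all(st2$cell_y >= 0 & st2$cell_y < p2$X))

  expect_error(init_population(sim_params(dim = 1, L = 0.4, dx = 0.1, K = 1)),
               "below 1")
})

test_that("reproduction rate follows the cost/benefit/competition form", {
  p <- sim_params(dim = 1)  # g0 = 5, b_max = 2, b0 = 0.5, K = 100
  expect_equal(reproduction_rate(0, 0, 0, p), 5)
  expect_equal(reproduction_rate(0.3, 0, 100, p), 0)       # D = K
  expect_equal(reproduction_rate(0.7, 5, 100, p), 0)
  expect_equal(reproduction_rate(0, 1e12, 0, p), 15, tolerance = 1e-9)  # saturation g0*(1+b_max)
  expect_equal(reproduction_rate(2, 0, 50, p), 0)          # factor 1 negative -> clamp
  # negative traits act as phi_E = 0
  expect_equal(reproduction_rate(-0.4, 0.2, 10, p),
               reproduction_rate(0, 0.2, 10, p))
})

test_that("mutation kicks have mean size m, random sign, and respect the trait mode", {
  p0 <- sim_params(dim = 1, mu = 0)
  set.seed(2)
  phi <- runif(1000)
  set.seed(3)
  expect_identical(mutate_trait(phi, p0), phi)  # mu = 0: always inherited

  p1 <- sim_params(dim = 1, mu = 1)  # every offspring mutated
  set.seed(4)
  delta <- mutate_trait(rep(1, 1e5), p1) - 1
  m <- p1$m
  expect_equal(mean(abs(delta)), m, tolerance = 3 * m / sqrt(1e5) / m)  # 3 SE
  expect_equal(mean(sign(delta)), 0, tolerance = 3 / sqrt(1e5) * 1.5)

  pt <- sim_params(dim = 2, mu = 1)  # truncate mode
  set.seed(5)
  child <- mutate_trait(rep(0, 1e4), pt)
  expect_true(all(child >= 0))
  expect_true(any(child == 0))  # negative kicks floored at zero
})

test_that("degenerate runs behave: T = 0, empty start, frozen demography", {
  p <- sim_params(dim = 1, L = 25.6, dx = 0.1, T = 0, seed = 2)
  r0 <- run_simulation(p, T = 0)
  expect_equal(nrow(r0$series), 1L)
  expect_equal(r0$series$t, 0)
  expect_false(r0$extinct)

  empty <- data.frame(cell_x = integer(0), phi = numeric(0))
  re <- run_simulation(p, T = 8, init_state = empty)
  expect_true(re$extinct)

  # (near-)zero death and reproduction: count conserved, positions change
  pf <- sim_params(dim = 1, L = 25.6, dx = 0.1, g0 = 1e-9, d = 1e-9,
                   K = 1, T = 8, seed = 3)
  st <- data.frame(cell_x = rep(128L, 200L), phi = 0)
  rf <- run_simulation(pf, T = 8, init_state = st)
  expect_equal(nrow(rf$final), 200L)
  expect_gt(var(rf$final$cell_x), 0)
})

test_that("one-step survivor counts match the expected offspring number", {
  # many well-separated individuals at negligible density: g ~ g0, so the
  # realized mean offspring over 10^4 parents estimates (1+g0*dt)(1-d*dt)
  p <- sim_params(dim = 1, L = 102.4, dx = 0.1, K = 1e5, T = 0, seed = 9)
  set.seed(9)
  st <- data.frame(cell_x = sample(0:(p$X - 1), 1e4, replace = TRUE), phi = 0)
  r <- run_simulation(p, T = p$dt, init_state = st, interval_length = NULL)
  ew <- (1 + p$g0 * p$dt) * (1 - p$d * p$dt)  # 1.288
  expect_equal(nrow(r$final) / 1e4, ew, tolerance = 0.015)
})

test_that("random-walk displacement reproduces the scale of motility", {
  # g0, d ~ 0: pure walkers; RMS displacement per dimension after t
  # generations is sigma_m * sqrt(t) with sigma_m = sqrt(2 k_D / d) at d = 1
  p <- sim_params(dim = 1, L = 51.2, dx = 1 / 80, g0 = 1e-9, d = 1e-9,
                  K = 1, T = 0, seed = 10, k_D = 0.03)
  n <- 1e4
  x0 <- rep(2048L, n)
  st <- data.frame(cell_x = x0, phi = 0)
  t_gen <- 24.96  # 312 steps of dt = 0.08
  r <- run_simulation(p, T = t_gen, init_state = st, interval_length = NULL,
                      record_every = 1000)
  disp <- (r$final$cell_x - x0 + p$X / 2) %% p$X - p$X / 2
  rms <- sqrt(mean((disp * p$dx)^2))
  expect_equal(rms, sqrt(2 * 0.03 * t_gen), tolerance = 0.05)
})

test_that("identical seed and parameters give identical trajectories", {
  p <- sim_params(dim = 1, L = 25.6, dx = 0.1, T = 40, seed = 12)
  r1 <- run_simulation(p, init_phi = 0.05)
  r2 <- run_simulation(p, init_phi = 0.05)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$final, r2$final)
  expect_identical(r1$snapshots, r2$snapshots)
})

test_that("a defector population hovers near the carrying density", {
  p <- sim_params(dim = 1, L = 25.6, dx = 0.1, mu = 0, T = 400, seed = 13)
  r <- run_simulation(p, record_every = 25)
  s <- r$series
  late <- s$n[s$t >= 200] / p$L
  expect_equal(mean(late), (1 - p$d / p$g0) * p$K, tolerance = 0.05)
  expect_equal(max(abs(s$mean_phi)), 0)  # no mutation, defectors stay defectors
})
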