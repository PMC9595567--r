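test_that("strict local minima ignore constants and plateaus, find sine troughs", {
  expect_length(find_local_minima(rep(3, 64)), 0)

  x <- 0:255
  v <- 10 + sin(2 * pi * x / 256)
  expect_equal(find_local_minima(v), 192L)  # single trough

  # exact two-cell plateau minimum: strictness yields nothing
  v2 <- c(5, 4, 3, 3, 4, 5, 6, 7)
  expect_length(find_local_minima(v2), 0)
  # but a one-cell minimum is found (0-based index)
  v3 <- c(5, 4, 3, 4, 5, 6, 7, 6)
  expect_equal(find_local_minima(v3), 2L)
})

test_that("tentative borders use the high threshold and the derivative rule", {
  K <- 100
  # trough at cell 10 with rho = 80 = 0.8K: discarded; trough at 30 with 50: kept
  x <- 0:63
  v <- 90 - 10 * exp(-(x - 10)^2 / 8) - 40 * exp(-(x - 30)^2 / 8)
  mins <- find_local_minima(v)
  tb <- place_tentative_borders(v, mins, T_high = 0.7 * K)
  expect_equal(tb$min_cell, 30L)
  expect_equal(tb$rho_min, 50, tolerance = 0.01)

  # asymmetric minimum, falling to the right: border after the minimum
  vr <- c(9, 7, 5, 4.6, 4.5, 6, 8, 9)   # min at cell 4, rho'(4) < 0... check
  # rho'(4) = (v[6] - v[4])/2 = (6 - 4.6)/2 > 0 -> border between 3 and 4
  tb2 <- place_tentative_borders(vr, find_local_minima(vr), 70)
  expect_equal(tb2$border, 3.5)

  # symmetric minimum: derivative zero, border placed after the minimum cell
  vs <- c(9, 7, 5, 4, 5, 7, 9, 9.5)
  tb3 <- place_tentative_borders(vs, find_local_minima(vs), 70)
  expect_equal(tb3$border, 3.5)
})

test_that("partitions tile the habitat and account for every individual", {
  fx <- make_fixture("two_clusters")
  tr <- track_colonies(list(fx$state), fx$params)
  part <- tr$partitions[[1]]
  expect_equal(nrow(part$colonies), 2L)
  expect_equal(sum(part$colonies$n), nrow(fx$state))
  expect_equal(sort(unique(part$membership)), c(1L, 2L))
  # colony mean traits recover the construction
  expect_equal(sort(part$colonies$Phi), c(0.02, 0.08))
  # borders on half-integers
  expect_true(all(part$borders$border %% 1 == 0.5))
})

test_that("ancestor assignment uses plurality with size and index tie-breaks", {
  part1 <- structure(list(
    membership = c(1L, 1L, 1L, 2L, 2L, 2L, 2L),
    colonies = data.frame(id = 1:2, n = c(3L, 4L), Phi = c(0.1, 0),
                          com = c(10, 50))), class = "colony_partition")
  # 60/40-style split: plurality wins (3 of 5 ancestors sit in colony 1)
  expect_equal(assign_ancestors(rep(1L, 5), 1L, c(1L, 2L, 3L, 4L, 5L), part1), 1L)
  # exact 50/50: larger t1 colony (colony 2) wins
  expect_equal(assign_ancestors(rep(1L, 4), 1L, c(1L, 2L, 4L, 5L), part1), 2L)
  # equal sizes: lower index wins
  part_eq <- part1
  part_eq$colonies$n <- c(3L, 3L)
  part_eq$membership <- c(1L, 1L, 1L, 2L, 2L, 2L)
  expect_equal(assign_ancestors(rep(1L, 4), 1L, c(1L, 2L, 4L, 5L), part_eq), 1L)
})

test_that("fission, extinction, and shallow-dip fixtures get the right events", {
  fx <- make_fixture("fission")
  tr <- track_colonies(list(fx$state1, fx$state2), fx$params)
  ev <- tr$events[[1]]
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$V, 2L)
  expect_equal(ev$label, "fission")
  expect_equal(nrow(tr$partitions[[2]]$colonies), 2L)

  fx <- make_fixture("extinction")
  tr <- track_colonies(list(fx$state1, fx$state2), fx$params)
  ev <- tr$events[[1]]
  dead <- ev[ev$V == 0L, ]
  expect_equal(nrow(dead), 1L)
  expect_equal(dead$label, "extinct")
  expect_equal(dead$Phi, fx$extinct_Phi_t1)
  expect_equal(ev$V[ev$Phi > 0.05], 1L)

  fx <- make_fixture("shallow_dip")
  g <- fx$grid
  rho <- smooth_density(fx$state2, g)
  saddle <- rho$values[find_local_minima(rho) + 1]
  saddle <- saddle[saddle > 1]  # the interior dip (empty-space minima ~ 0)
  expect_true(all(saddle > 0.2 * fx$params$K & saddle < 0.7 * fx$params$K))
  tr <- track_colonies(list(fx$state1, fx$state2), fx$params)
  expect_equal(nrow(tr$partitions[[2]]$colonies), 1L)
  expect_equal(tr$events[[1]]$V, 1L)
  expect_equal(tr$events[[1]]$label, "survived")
})

test_that("hysteresis keeps an oscillating border without fission/fusion chatter", {
  ot <- make_oscillating_trace(n_oscillations = 3)
  # precondition: after the split the gap minimum oscillates between the
  # thresholds' neighbourhood (never above T_high, sometimes above T_low)
  gaps <- sapply(ot$snapshots[-(1:2)], function(s) {
    rho <- smooth_density(s, ot$grid)
    mins <- rho$values[find_local_minima(rho) + 1]
    max(mins[mins > 1])  # interior gap minimum
  })
  expect_true(all(gaps < 0.7 * ot$params$K))
  expect_true(any(gaps > 0.2 * ot$params$K))

  tr <- track_colonies(ot$snapshots, ot$params)
  counts <- vapply(tr$partitions, function(p) nrow(p$colonies), integer(1))
  expect_equal(counts, c(1L, rep(2L, length(ot$snapshots) - 1L)))
  # one fission event, then only survivals: no chatter
  expect_equal(tr$events[[1]]$V, 2L)
  for (e in tr$events[-1]) expect_equal(e$V, c(1L, 1L))
})

test_that("the colony table carries lineage rows for every boundary", {
  fx <- make_fixture("fission")
  tr <- track_colonies(list(fx$state1, fx$state2), fx$params)
  tab <- tr$table
  expect_equal(sort(unique(tab$boundary)), c(0L, 1L))
  expect_equal(sum(tab$n[tab$boundary == 1]), nrow(fx$state2))
  expect_true(all(tab$ancestor[tab$boundary == 1] == 1L))
  tmp <- tempfile(fileext = ".tsv")
  write_lineage(tr, tmp)
  back <- read.delim(tmp)
  expect_equal(nrow(back), nrow(tab))
})
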