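test_that("local density counts occupied Moore squares", {
  p <- tiny_params(vessel_count = 0L)
  vm <- build_vessel_map(p, rng_streams(1))
  expect_identical(local_density(c(210, 210), NULL, vm), 0L)
  ring <- cbind(210 + 20 * c(1, 1, 0, -1, -1, -1, 0, 1),
                210 + 20 * c(0, 1, 1, 1, 0, -1, -1, -1))
  expect_equal(local_density(c(210, 210), ring, vm), 8L)

  # random 50-cell configuration vs. an independent per-cell scan
  set.seed(42)
  pts <- cbind(runif(50, 0, p$L), runif(50, 0, p$L))
  nx <- vm$nx
  for (i in 1:50) {
    got <- local_density(pts[i, ], pts[-i, ], vm)
    mysq <- floor(pts[i, 1] / 20) + nx * floor(pts[i, 2] / 20)
    osq <- floor(pts[-i, 1] / 20) + nx * floor(pts[-i, 2] / 20)
    mx <- mysq %% nx; my <- mysq %/% nx
    want <- 0L
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      nb <- ((mx + dx) %% nx) + nx * ((my + dy) %% nx)
      if (any(osq == nb)) want <- want + 1L
    }
    expect_equal(got, want)
  }
})

test_that("proliferation score is T plus crowding and vessel bonuses", {
  p <- model_params(tau = 24, t_G1 = 8, delta_D = 4)
  expect_equal(proliferation_score(20, 0, FALSE, p), 24)
  expect_equal(proliferation_score(0, 8, FALSE, p), 0)
  # nourished bonus makes the effective cycle tau / 1.3
  dV <- proliferation_score(10, 3, TRUE, p) - proliferation_score(10, 3, FALSE, p)
  expect_equal(dV, 24 * (1 - 1 / 1.3), tolerance = 1e-12)
  expect_equal(dV, 24 - 24 / 1.3, tolerance = 1e-12)
  expect_error(proliferation_score(10, 9, FALSE, p), "0..8")
  # monotone: decreasing in n, increasing in T
  expect_true(all(diff(proliferation_score(10, 0:8, FALSE, p)) < 0))
  expect_true(all(diff(proliferation_score(seq(0, 48, 4), 2, FALSE, p)) > 0))
})

test_that("division probability switches on PS, G1 fast track and crowding", {
  p <- model_params(tau = 24, t_G1 = 8)
  expect_equal(division_probability(100, 8, FALSE, p), 0)
  expect_equal(division_probability(24, 3, FALSE, p), p$p_div_high)
  expect_equal(division_probability(10, 3, TRUE, p), p$p_div_high)
  expect_equal(division_probability(10, 3, FALSE, p), p$p_div_low)
  # monotone non-decreasing in PS, non-increasing in n
  for (g1 in c(TRUE, FALSE)) {
    ps <- division_probability(seq(0, 48, 2), 4, g1, p)
    expect_true(all(diff(ps) >= 0))
    pn <- division_probability(30, 0:8, g1, p)
    expect_true(all(diff(pn) <= 0))
  }
})

test_that("G1 fast track engages at the phase boundary", {
  p <- model_params(tau = 24, t_G1 = 8)
  expect_true(g1_fast_track(8, p))
  expect_true(g1_fast_track(12, p))
  expect_false(g1_fast_track(0, p))
  expect_false(g1_fast_track(8 - 1, p))
})

test_that("fate classification brackets quiescence between n_s and n_n", {
  p <- model_params(tau = 24, t_G1 = 8, n_s = 2L, n_n = 3L)
  expect_identical(classify_fate(3 * 24, p), "necrotic")
  expect_identical(classify_fate(2.5 * 24, p), "quiescent")
  expect_identical(classify_fate(2 * 24, p), "quiescent")
  expect_identical(classify_fate(0, p), "proliferating")
  expect_identical(classify_fate(c(0, 60, 72), p),
                   c("proliferating", "quiescent", "necrotic"))
})

test_that("daughter placement uses free Moore spots under the persistence rule", {
  p <- tiny_params(vessel_count = 0L)
  vm <- build_vessel_map(p, rng_streams(1))
  s <- rng_streams(17)
  mother <- c(210, 210)

  # all free, persistence 1, heading East: forward spot at d or sqrt(2) d
  for (i in 1:50) {
    out <- place_daughter(list(position = mother, heading = 0L,
                               persistence = 1), vm, NULL, p, s)
    expect_true(out$success)
    off <- out$position - mother
    expect_true(sqrt(sum(off^2)) %in% c(20, sqrt(2) * 20) ||
                  abs(sqrt(sum(off^2)) - sqrt(2) * 20) < 1e-9)
    ang <- atan2(off[2], off[1])
    expect_lte(abs(ang), pi / 2 + 1e-9)  # within bilateral 90 deg of East
    expect_equal(out$mother_T, 0)        # division clock reset on success
  }

  # no free spot: division fails, clock untouched
  ring <- cbind(210 + 20 * c(1, 1, 0, -1, -1, -1, 0, 1),
                210 + 20 * c(0, 1, 1, 1, 0, -1, -1, -1))
  out <- place_daughter(list(position = mother, heading = 0L,
                             persistence = 1), vm, ring, p, s)
  expect_false(out$success)
  expect_gt(out$mother_T, 0)

  # exactly one free spot: daughter lands there with probability 1
  seven <- ring[-3, ]  # free North spot only
  for (i in 1:10) {
    out <- place_daughter(list(position = mother, heading = 0L,
                               persistence = 0.5), vm, seven, p, s)
    expect_true(out$success)
    expect_equal(out$position, c(210, 230))
  }
})

test_that("a packed cluster develops a necrotic core within n_n cycles", {
  p <- tiny_params(n_init = 25L, duration = 3 * 24 + 12)
  r <- run_simulation(p, const_phenotypes(speed = 0), seed = 2,
                      record_every = 12)
  expect_gt(tail(r$cumulative_necrotic, 1), 0)
  # no necrosis can occur before n_n * tau
  before <- r$timepoints < 3 * 24
  expect_true(all(r$cumulative_necrotic[before] == 0))
})
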