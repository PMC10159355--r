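test_that("wrap_position maps onto the half-open periodic domain", {
  expect_equal(wrap_position(c(2010, 5), 2000), c(10, 5))
  expect_equal(wrap_position(c(-5, 1999), 2000), c(1995, 1999))
  expect_equal(wrap_position(c(2000, 0), 2000), c(0, 0))
})

test_that("forward and backward heading sets partition the 8 directions", {
  for (h in 0:7) {
    hs <- heading_set(h)
    expect_length(hs$forward, 5)
    expect_length(hs$backward, 3)
    expect_setequal(c(hs$forward, hs$backward), 0:7)
    expect_length(intersect(hs$forward, hs$backward), 0)
    # forward = within bilateral 90 degrees inclusive of the previous heading
    diffs <- (hs$forward - h) %% 8
    expect_true(all(diffs %in% c(0, 1, 2, 6, 7)))
  }
})

test_that("sample_speed honors constant and empirical profiles", {
  s <- rng_streams(4)
  expect_identical(sample_speed(30, s), 30)
  expect_identical(sample_speed(0, s), 0)
  draws <- vapply(1:1e4, function(i) sample_speed(c(10, 20, 30), s),
                  numeric(1))
  expect_true(all(draws %in% c(10, 20, 30)))
  sigma <- sd(c(10, 20, 30)) / sqrt(1e4)
  expect_lt(abs(mean(draws) - 20), 3 * sigma + 0.1)
  expect_error(sample_speed(numeric(0), s), "empty")
})

test_that("persistence gates the heading set of a proposed move", {
  p <- tiny_params(vessel_count = 0L)
  vm <- build_vessel_map(p, rng_streams(1))
  s <- rng_streams(2)
  none <- matrix(numeric(0), ncol = 2)
  for (i in 1:100) {
    mv <- propose_move(list(position = c(200, 200), heading = 0L,
                            persistence = 1, speed = 10),
                       vm, none, p, s)
    expect_true(mv$heading %in% c(6, 7, 0, 1, 2))
  }
  for (i in 1:100) {
    mv <- propose_move(list(position = c(200, 200), heading = 0L,
                            persistence = 0, speed = 10),
                       vm, none, p, s)
    expect_true(mv$heading %in% c(3, 4, 5))
  }
})

test_that("step length equals speed times dt", {
  p <- tiny_params(vessel_count = 0L)
  vm <- build_vessel_map(p, rng_streams(1))
  s <- rng_streams(9)
  mv <- propose_move(list(position = c(200, 200), heading = NA,
                          persistence = 0.5, speed = 30),
                     vm, NULL, p, s)
  expect_equal(sqrt(sum((mv$position - c(200, 200))^2)), 30, tolerance = 1e-9)
})

test_that("a fully enclosed cell stays put and keeps its heading", {
  p <- tiny_params(vessel_count = 0L)
  vm <- build_vessel_map(p, rng_streams(1))
  s <- rng_streams(3)
  ring <- cbind(200 + 20 * c(1, 1, 0, -1, -1, -1, 0, 1),
                200 + 20 * c(0, 1, 1, 1, 0, -1, -1, -1))
  mv <- propose_move(list(position = c(200, 200), heading = 2L,
                          persistence = 0.5, speed = 5),
                     vm, ring, p, s)
  expect_identical(mv$outcome, "stayed")
  expect_equal(mv$position, c(200, 200))
  expect_identical(mv$heading, 2L)
})

test_that("pairwise non-overlap survives a crowded simulation", {
  p <- tiny_params(duration = 96, n_init = 9L)
  r <- run_simulation(p, const_phenotypes(speed = 15), seed = 13,
                      record_every = 24)
  xy <- as.matrix(r$final_positions[, c("x", "y")])
  expect_lte(nrow(xy), 200)  # brute-force all-pairs oracle scale
  dd <- periodic_dist(xy, p$L)
  diag(dd) <- Inf
  expect_gte(min(dd), p$d_cell - 1e-6)
})

test_that("long-run forward-move fraction matches the persistence ratio", {
  pers <- 0.7
  tr <- generate_tracks(10, pers, n_tracks = 100, n_steps = 60, seed = 6)
  fwd <- unlist(lapply(split(tr, tr$track_id), function(t1) {
    vx <- diff(t1$x); vy <- diff(t1$y)
    keep <- vx != 0 | vy != 0
    vx <- vx[keep]; vy <- vy[keep]
    if (length(vx) < 2) return(logical(0))
    # consecutive step directions within 90 degrees = forward-set move
    dot <- vx[-1] * vx[-length(vx)] + vy[-1] * vy[-length(vy)]
    dot >= -1e-9
  }))
  n <- length(fwd)
  expect_lt(abs(mean(fwd) - pers), 3 * sqrt(pers * (1 - pers) / n))
})

test_that("persistent walkers outrun anti-persistent walkers", {
  net <- function(pp) {
    tr <- generate_tracks(10, pp, n_tracks = 80, n_steps = 60, seed = 14)
    mean(vapply(split(tr, tr$track_id), function(t1) {
      sqrt((tail(t1$x, 1) - t1$x[1])^2 + (tail(t1$y, 1) - t1$y[1])^2)
    }, numeric(1)))
  }
  expect_gt(net(1), net(0))
})

test_that("nourished-zone residence decreases with the exit probability", {
  mean_nour <- function(pex) {
    p <- tiny_params(vessel_count = 2L, nourished_radius = 100,
                     p_exit_nourished = pex, duration = 96)
    mean(vapply(1:5, function(s) {
      run_simulation(p, const_phenotypes(speed = 20), seed = s,
                     record_every = 96)$mean_nourished_time
    }, numeric(1)))
  }
  expect_gt(mean_nour(0.05), mean_nour(0.95))
})
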