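test_that("trigger obeys the u <= p contract at the extremes", {
  s <- rng_streams(1)
  expect_false(any(vapply(1:50, function(i) trigger(0, s), logical(1))))
  expect_true(all(vapply(1:50, function(i) trigger(1, s), logical(1))))
  expect_error(trigger(-0.1, s), "probability")
  expect_error(trigger(1.5, s), "probability")
})

test_that("trigger frequency is binomially calibrated", {
  s <- rng_streams(321)
  for (p in c(0.0001, 0.01, 0.5)) {
    n <- 1e6
    hits <- sum(draw_uniform(s, n, "division") <= p)
    expect_lt(abs(hits - n * p), 3 * sqrt(n * p * (1 - p)) + 1)
  }
})

test_that("uniform draws lie in (0, 1] so p = 0 can never fire", {
  s <- rng_streams(7)
  u <- draw_uniform(s, 1e5, "movement")
  expect_true(all(u > 0 & u <= 1))
})

test_that("process streams are independent and seed-reproducible", {
  a <- rng_streams(42)
  b <- rng_streams(42)
  expect_identical(draw_uniform(a, 10, "movement"),
                   draw_uniform(b, 10, "movement"))
  # draws from one stream do not perturb another
  c1 <- rng_streams(42)
  invisible(draw_uniform(c1, 1000, "intravasation"))
  expect_identical(draw_uniform(c1, 10, "movement"),
                   draw_uniform(rng_streams(42), 10, "movement"))
  # distinct streams produce distinct sequences
  d <- rng_streams(42)
  expect_false(isTRUE(all.equal(draw_uniform(d, 10, "movement"),
                                draw_uniform(d, 10, "division"))))
})

test_that("validate_params fills defaults and enforces invariants", {
  p <- validate_params(list(n_s = 2L, n_n = 3L))
  expect_s3_class(p, "model_params")
  expect_identical(p$n_n, 3L)
  expect_silent(validate_params(list(p_intr = 1e-4)))
  expect_error(validate_params(list(n_s = 3L, n_n = 3L)), "n_s")
  expect_error(validate_params(list(p_div_high = 1.2)), "p_div_high")
  expect_error(validate_params(list(p_intr = -0.1)), "p_intr")
  expect_error(validate_params(list(tau = 24, t_G1 = 24)), "t_G1")
  expect_error(validate_params(list(dt = 0)), "dt")
  expect_error(validate_params(list(bogus_key = 1)), "unknown parameter")
  expect_error(validate_params(list(L = 410)), "multiple")
})

test_that("identical seed and params give a bit-identical simulation", {
  p <- tiny_params(duration = 96)
  r1 <- run_simulation(p, const_phenotypes(), seed = 11, record_every = 24)
  r2 <- run_simulation(p, const_phenotypes(), seed = 11, record_every = 24)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(r1$cells, r2$cells)
  r3 <- run_simulation(p, const_phenotypes(), seed = 12, record_every = 24)
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
})

test_that("cell-count conservation holds at every recording point", {
  p <- tiny_params(duration = 120, n_init = 4L)
  r <- run_simulation(p, const_phenotypes(speed = 15), seed = 5,
                      record_every = 12)
  expect_equal(r$alive_count,
               p$n_init + r$cumulative_births - r$cumulative_necrotic -
                 r$cumulative_intravasated)
  expect_true(all(diff(r$cumulative_intravasated) >= 0))
  expect_true(all(diff(r$cumulative_necrotic) >= 0))
  expect_true(all(diff(r$cumulative_births) >= 0))
  expect_true(all(r$alive_count >= 0) && all(r$quiescent_count >= 0))
})

test_that("config files round-trip through validation", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("L: 600", "vessel_count: 4", "tau: 24", "t_G1: 8",
               "p_intr: 1.0e-4"), f)
  p <- read_config(f)
  expect_s3_class(p, "model_params")
  expect_equal(p$L, 600)
  expect_identical(p$vessel_count, 4L)
  expect_equal(p$p_intr, 1e-4)

  fj <- tempfile(fileext = ".json")
  writeLines('{"L": 600, "tau": 24, "t_G1": 8,
               "vessel_coords": [[100, 100], [300, 300]]}', fj)
  pj <- read_config(fj)
  expect_equal(nrow(attr(pj, "vessel_coords")), 2)
  vm <- build_vessel_map(pj, rng_streams(1))
  expect_identical(length(vm$lumen), 2L)

  bad <- tempfile(fileext = ".yaml")
  writeLines("nonsense_key: 1", bad)
  expect_error(read_config(bad), "unknown parameter")
  expect_error(read_config(tempfile(fileext = ".txt")), "yaml")
  unlink(c(f, fj, bad))
})
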