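test_that("rms speed matches closed-form cases", {
  tr <- data.frame(t = 0:3, x = c(0, 30, 60, 90), y = 0)
  expect_equal(rms_speed(tr), 30)
  expect_equal(rms_speed(data.frame(t = 0:5, x = 1, y = 2)), 0)
  two <- data.frame(t = 0:2, x = c(0, 30, 70), y = 0)
  expect_equal(rms_speed(two), sqrt((900 + 1600) / 2))  # ~35.355
  expect_error(rms_speed(data.frame(t = c(0, 1, 3), x = 1:3, y = 0)),
               "uniform")
  expect_error(rms_speed(data.frame(t = 0, x = 1, y = 1)), "2 samples")
})

test_that("persistence ratio is net displacement over path length", {
  straight <- data.frame(t = 0:4, x = seq(0, 40, 10), y = seq(0, 80, 20))
  expect_equal(persistence_ratio(straight), 1)
  loop <- data.frame(t = 0:4, x = c(0, 10, 10, 0, 0), y = c(0, 0, 10, 10, 0))
  expect_equal(persistence_ratio(loop), 0)
  lpath <- data.frame(t = 0:2, x = c(0, 30, 30), y = c(0, 0, 40))
  expect_equal(persistence_ratio(lpath), 50 / 70)
  expect_error(persistence_ratio(data.frame(t = 0:2, x = 1, y = 1)),
               "zero path")
})

test_that("track statistics are invariant to translation and rotation", {
  set.seed(5)
  tr <- data.frame(t = 0:20, x = cumsum(rnorm(21, 2)), y = cumsum(rnorm(21)))
  th <- 37 * pi / 180
  rot <- data.frame(t = tr$t,
                    x = cos(th) * tr$x - sin(th) * tr$y + 120,
                    y = sin(th) * tr$x + cos(th) * tr$y - 55)
  expect_equal(rms_speed(rot), rms_speed(tr), tolerance = 1e-9)
  expect_equal(persistence_ratio(rot), persistence_ratio(tr),
               tolerance = 1e-9)
})

test_that("persistence ratio never exceeds one on simulated walks", {
  tr <- generate_tracks(c(5, 10, 20), 0.5, n_tracks = 40, n_steps = 30,
                        seed = 9)
  ratios <- vapply(split(tr, tr$track_id), persistence_ratio, numeric(1))
  expect_true(all(ratios <= 1 + 1e-12))
})

test_that("group assignment scales by population means with ties going high", {
  mk <- function(id, step, straight) {
    n <- 20
    if (straight) {
      x <- seq(0, by = step, length.out = n)
      y <- rep(0, n)
    } else {
      x <- rep(c(0, step), length.out = n)
      y <- rep(0, n)
    }
    data.frame(track_id = id, frame = seq_len(n) - 1, t = seq_len(n) - 1,
               x = x, y = y)
  }
  tracks <- rbind(mk("a", 5, FALSE), mk("b", 5, TRUE),
                  mk("c", 40, FALSE), mk("d", 40, TRUE))
  g <- assign_groups(tracks)
  got <- setNames(g$tracks$group, g$tracks$track_id)
  expect_identical(got[["a"]], 1L)  # slow, zigzag
  expect_identical(got[["b"]], 2L)  # slow, straight
  expect_identical(got[["c"]], 3L)  # fast, zigzag
  expect_identical(got[["d"]], 4L)  # fast, straight
  expect_equal(g$abundances, rep(0.25, 4))
  expect_equal(sum(g$abundances), 1)
  expect_equal(mean(g$tracks$scaled_speed), 1)
  expect_equal(mean(g$tracks$scaled_persistence), 1)

  # identical tracks sit exactly on both means: boundary goes to group 4
  twin <- rbind(mk("t1", 10, TRUE), mk("t2", 10, TRUE))
  g2 <- assign_groups(twin)
  expect_identical(unique(g2$tracks$group), 4L)
  expect_error(assign_groups(mk("solo", 10, TRUE)), "2 tracks")
})

test_that("the generator recovers its input parameters", {
  expect_error(generate_tracks(10, 1.5), "persistence")
  # zero speed: stationary tracks
  still <- generate_tracks(0, 0.5, n_tracks = 3, n_steps = 5, seed = 1)
  expect_true(all(still$x == 0 & still$y == 0))
  # deterministic under seed
  a <- generate_tracks(10, 0.5, n_tracks = 5, n_steps = 10, seed = 3)
  expect_identical(a, generate_tracks(10, 0.5, n_tracks = 5, n_steps = 10,
                                      seed = 3))
  # speed recovery within 5% over 200 tracks
  tr <- generate_tracks(20, 0.5, n_tracks = 200, n_steps = 60, seed = 4)
  sp <- vapply(split(tr, tr$track_id), rms_speed, numeric(1))
  expect_lt(abs(mean(sp) - 20) / 20, 0.05)
  # input persistence maps monotonically onto the measured ratio
  lv <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  pr <- vapply(lv, function(pp) {
    t2 <- generate_tracks(10, pp, n_tracks = 60, n_steps = 60, seed = 8)
    mean(vapply(split(t2, t2$track_id), persistence_ratio, numeric(1)))
  }, numeric(1))
  expect_gt(cor(lv, pr, method = "spearman"), 0.9)
})

test_that("track tables round-trip through CSV", {
  tr <- generate_tracks(10, 0.5, n_tracks = 2, n_steps = 5, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_tracks(tr, f)
  back <- read_tracks(f)
  expect_equal(as.data.frame(lapply(back, as.numeric)),
               as.data.frame(lapply(tr, as.numeric)), tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_tracks(bad), "columns")
  unlink(c(f, bad))
})
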