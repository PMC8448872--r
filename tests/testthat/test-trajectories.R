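test_that("to_speed_series computes Euclidean displacement over dt", {
  expect_equal(to_speed_series(trajectory("a", c(0, 1), c(0, 3), c(0, 4)))$values,
               5)
  expect_equal(to_speed_series(trajectory("b", c(0, 2), c(1, 1), c(1, 1)))$values,
               0)
  # brute-force loop oracle on random points
  set.seed(11)
  t <- cumsum(runif(10, 0.5, 2)); x <- rnorm(10); y <- rnorm(10)
  tr <- trajectory("r", t, x, y, 1L, 1L)
  oracle <- vapply(2:10, function(i)
    sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2) / (t[i] - t[i - 1]), 0)
  s <- to_speed_series(tr)
  expect_equal(s$values, oracle, tolerance = 1e-12)
  expect_identical(s$class_label, 1L)
  expect_identical(s$domain_label, 1L)
  expect_false(s$normalized)
})

test_that("trajectory invariants are enforced", {
  expect_error(trajectory("a", c(0, 0), c(0, 1), c(0, 1)), "increasing")
  expect_error(trajectory("a", 0, 0, 0), "2 points")
  expect_error(trajectory("a", 0:1, 0:1, 0:1, class_label = 2), "0 or 1")
  expect_no_error(to_speed_series(trajectory("a", c(0, 1e-9, 1), 0:2, 0:2)))
  expect_error(to_speed_series(
    structure(list(id = "a", t = c(0, 0, 1), x = 0:2, y = 0:2,
                   class_label = 0L, domain_label = 0L),
              class = "loco_trajectory")), "zero dt")
})

test_that("speed conversion is rigid-motion invariant and scales linearly", {
  set.seed(21)
  for (rep in 1:5) {
    t <- cumsum(runif(15, 0.2, 1)); x <- rnorm(15); y <- rnorm(15)
    base <- to_speed_series(trajectory("p", t, x, y))$values
    th <- runif(1, 0, 2 * pi); dx <- rnorm(1); dy <- rnorm(1)
    xr <- cos(th) * x - sin(th) * y + dx
    yr <- sin(th) * x + cos(th) * y + dy
    expect_equal(to_speed_series(trajectory("p", t, xr, yr))$values, base,
                 tolerance = 1e-10)
    cc <- runif(1, 0.1, 50)
    scaled <- to_speed_series(trajectory("p", t, cc * x, cc * y))$values
    expect_equal(scaled, cc * base, tolerance = 1e-10)
    # scale invariance after z-scoring: what cross-species comparison rests on
    expect_equal(
      normalize_series(to_speed_series(trajectory("p", t, cc * x, cc * y)))$values,
      normalize_series(to_speed_series(trajectory("p", t, x, y)))$values,
      tolerance = 1e-9)
  }
})

test_that("normalize_series z-scores with the population std", {
  s <- normalize_series(make_series(c(1, 2, 3), normalized = FALSE))
  expect_equal(s$values, c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-4)
  expect_true(s$normalized)
  expect_equal(mean(s$values), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(s$values^2)), 1, tolerance = 1e-9)
  expect_error(normalize_series(make_series(rep(2, 5), normalized = FALSE)),
               "zero variance")
  # idempotence within tolerance
  twice <- normalize_series(s)
  expect_equal(twice$values, s$values, tolerance = 1e-9)
})

test_that("resample_to_length is even-stride subsampling keeping the head", {
  s <- make_series(0:5)
  expect_equal(resample_to_length(s, 3)$values, c(0, 2, 4))
  expect_equal(resample_to_length(s, 6)$values, 0:5)
  expect_equal(resample_to_length(s, 1)$values, 0)
  expect_error(resample_to_length(s, 7), "target_len")
  set.seed(3)
  long <- make_series(rnorm(600), class_label = 1L, domain_label = 1L)
  out <- resample_to_length(long, 599)
  expect_length(out$values, 599)
  expect_identical(out$class_label, 1L)
  expect_identical(out$domain_label, 1L)
  expect_equal(out$values[1], long$values[1])
})

test_that("segment_trajectory splits, drops remainders and still segments", {
  t <- 0:600
  set.seed(7)
  tr <- trajectory("m", t, cumsum(rnorm(601)), cumsum(rnorm(601)))
  segs <- segment_trajectory(tr, 150)
  expect_length(segs, 4L)
  expect_true(all(vapply(segs, function(s) diff(range(s$t)) <= 150, TRUE)))

  still <- trajectory("still", 0:300, rep(0, 301), rep(0, 301))
  expect_length(segment_trajectory(still, 150, min_movement = 1), 0L)

  # mixed: brute-force window filter oracle
  x <- c(cumsum(rnorm(301)), rep(0, 300))  # moving first half, parked after
  y <- c(cumsum(rnorm(301)), rep(0, 300))
  x[302:601] <- x[301]; y[302:601] <- y[301]
  tr2 <- trajectory("mix", 0:600, x, y)
  kept <- segment_trajectory(tr2, 150, min_movement = 5)
  oracle_kept <- sum(vapply(1:4, function(k) {
    ix <- ((k - 1) * 150 + 1):(k * 150 + 1)
    sum(sqrt(diff(x[ix])^2 + diff(y[ix])^2)) >= 5
  }, TRUE))
  expect_length(kept, oracle_kept)
  # retained + dropped = floor(duration / window)
  expect_equal(length(segment_trajectory(tr2, 150, min_movement = 0)), 4L)
})

test_that("gait_to_stride_series detects strides and merges feet by onset", {
  rate <- 100
  square <- function(offset_s, period_s = 1, duty = 0.4, total_s = 8) {
    tt <- seq(0, total_s - 1 / rate, by = 1 / rate)
    as.numeric(((tt - offset_s) %% period_s) < duty * period_s &
                 tt >= offset_s)
  }
  f <- force_series("g", square(0), square(0.5), rate)
  s <- gait_to_stride_series(f, contact_threshold = 0.5)
  expect_true(all(abs(s$values - 1) < 1e-9))
  # event-list oracle: onsets at 0,1,..,7 (left) and 0.5,1.5,.. (right);
  # merged stride list sorted by onset interleaves feet strictly
  expect_length(s$values, 14L)  # 7 strides per foot
  f2 <- force_series("flat", rep(0, 800), rep(0, 800), rate)
  expect_error(gait_to_stride_series(f2, contact_threshold = 0.5),
               "insufficient gait")
})

test_that("trajectory / manifest / speed-series / config files round-trip", {
  dir <- withr::local_tempdir()
  tr <- trajectory("t1", c(0, 0.5, 1.2), c(0, 1, 3), c(2, 2, 1), 1L, 0L)
  write_trajectory(tr, file.path(dir, "t1.tsv"))
  back <- read_trajectory(file.path(dir, "t1.tsv"), "t1", 1L, 0L)
  expect_equal(back$x, tr$x)
  expect_equal(back$t, tr$t)

  mf <- data.frame(id = "t1", class = 1L, domain = 0L, path = "t1.tsv")
  write_manifest(mf, file.path(dir, "manifest.tsv"))
  cohort <- read_cohort(file.path(dir, "manifest.tsv"))
  expect_length(cohort, 1L)
  expect_identical(cohort[[1L]]$class_label, 1L)

  s <- make_series(rnorm(20), id = "sp", class_label = 1L, domain_label = 1L)
  write_speed_series(s, file.path(dir, "sp.speed"))
  s2 <- read_speed_series(file.path(dir, "sp.speed"))
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  expect_identical(s2$class_label, 1L)
  expect_true(s2$normalized)

  cfg <- list(epochs = 12, lr = 0.001, effect = "unstable-acceleration")
  write_config(cfg, file.path(dir, "cfg.txt"))
  cfg2 <- read_config(file.path(dir, "cfg.txt"))
  expect_equal(cfg2$epochs, 12)
  expect_equal(cfg2$lr, 0.001)
  expect_identical(cfg2$effect, "unstable-acceleration")
})
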