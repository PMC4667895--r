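test_that("fix tables parse into sorted per-animal trajectories", {
  win <- analysis_window(t0_utc, days = 50, season = "summer")
  rows <- data.frame(
    id = "594",
    timestamp = format(t0_utc + 3600 * 0:2, "%Y-%m-%dT%H:%M:%S"),
    x = c(1000, 1100, 1200), y = c(5000, 5050, 5100))
  tr <- parse_fix_table(rows, win)
  expect_named(tr, "594")
  expect_equal(n_fixes(tr[["594"]]), 3L)
  expect_equal(tr[["594"]]$fixes$x, c(1000, 1100, 1200))

  shuffled <- rows[c(3, 1, 2), ]
  tr2 <- parse_fix_table(shuffled, win)
  expect_equal(tr2[["594"]]$fixes, tr[["594"]]$fixes)
})

test_that("a missing hour is recorded as a 2-h gap, never interpolated", {
  win <- analysis_window(t0_utc, days = 50)
  hours <- setdiff(0:49, 20)
  rows <- data.frame(id = "a",
                     timestamp = format(t0_utc + 3600 * hours,
                                        "%Y-%m-%dT%H:%M:%S"),
                     x = 1000 + hours, y = 2000 + hours)
  tr <- parse_fix_table(rows, win)[["a"]]
  expect_equal(n_fixes(tr), 49L)
  expect_equal(nrow(tr$gaps), 1L)
  expect_equal(tr$gaps$gap_h, 2)
})

test_that("bad input is rejected with informative errors", {
  win <- analysis_window(t0_utc, days = 1)
  base <- data.frame(id = "a",
                     timestamp = format(t0_utc + 3600 * 0:1,
                                        "%Y-%m-%dT%H:%M:%S"),
                     x = c(1000, 1001), y = c(2000, 2001))
  bad_ts <- base; bad_ts$timestamp[2] <- "not-a-time"
  expect_error(parse_fix_table(bad_ts, win), "row")
  bad_xy <- base; bad_xy$x[1] <- "east"
  expect_error(parse_fix_table(bad_xy, win), "coordinate")
  dup <- base; dup$timestamp[2] <- dup$timestamp[1]
  expect_error(parse_fix_table(dup, win), "duplicate")
  lonlat <- base; lonlat$x <- c(34.6, 34.7); lonlat$y <- c(30.5, 30.6)
  expect_error(parse_fix_table(lonlat, win), "geographic")
  expect_error(trajectory("a", t0_utc + c(0, 0), c(0, 1), c(0, 1)),
               "duplicate")
})

test_that("fixes outside the window are dropped with a count", {
  win <- analysis_window(t0_utc, days = 1)
  tr <- trajectory("a", t0_utc + 3600 * c(-2, 0, 5, 30), 1:4 * 1000, 1:4)
  expect_equal(tr$n_dropped, 0L)  # self-derived window keeps all
  tr2 <- trajectory("a", t0_utc + 3600 * c(-2, 0, 5, 30), 1:4 * 1000, 1:4,
                    window = win)
  expect_equal(n_fixes(tr2), 2L)
  expect_equal(tr2$n_dropped, 2L)
})

test_that("parse -> serialize -> parse round-trips exactly", {
  win <- analysis_window(t0_utc, days = 2)
  tr <- list(a = trajectory("a", t0_utc + 3600 * 0:40,
                            cumsum(runif(41, 500, 700)),
                            cumsum(runif(41, 500, 700)), window = win))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fix_table(tr, path)
  tr2 <- parse_fix_table(path, win)
  expect_equal(tr2$a$fixes$x, tr$a$fixes$x)
  expect_equal(tr2$a$fixes$y, tr$a$fixes$y)
  expect_equal(as.numeric(tr2$a$fixes$time), as.numeric(tr$a$fixes$time))
})

test_that("step series has Euclidean distances and flags long steps", {
  tr <- make_traj(c(0, 300), c(0, 400))
  st <- step_series(tr)
  expect_equal(nrow(st), 1L)
  expect_equal(st$distance_m, 500)

  tr2 <- make_traj(rep(1000, 5), rep(1000, 5))
  expect_equal(step_series(tr2)$distance_m, rep(0, 4))

  tr3 <- trajectory("a", t0_utc + 3600 * c(0, 1, 3), c(0, 10, 20), c(0, 0, 0))
  st3 <- step_series(tr3)
  expect_equal(st3$duration_h, c(1, 2))
  expect_equal(st3$flagged, c(FALSE, TRUE))

  expect_equal(nrow(step_series(make_traj(0, 0))), 0L)
})

test_that("step distances are invariant to translation and rotation", {
  set.seed(11)
  x <- cumsum(rnorm(50, sd = 200)); y <- cumsum(rnorm(50, sd = 200))
  d0 <- step_series(make_traj(x, y))$distance_m
  expect_equal(step_series(make_traj(x + 5000, y - 3000))$distance_m, d0)
  th <- 0.7
  xr <- x * cos(th) - y * sin(th); yr <- x * sin(th) + y * cos(th)
  expect_equal(step_series(make_traj(xr, yr))$distance_m, d0)
})

test_that("step durations over a contiguous run sum to its time coverage", {
  tr <- make_traj(1:30 * 100, rep(0, 30))
  st <- step_series(tr)
  span_h <- diff(range(as.numeric(tr$fixes$time))) / 3600
  expect_equal(sum(st$duration_h), span_h)
})

test_that("clock hour uses the local timezone and snaps within tolerance", {
  t_local <- as.POSIXct("2013-08-12 14:00:00", tz = "Asia/Jerusalem")
  expect_identical(hour_of_day(t_local), 14L)
  expect_identical(hour_of_day(as.POSIXct("2013-08-12 13:58:00", tz = "UTC")),
                   14L)
  expect_identical(hour_of_day(as.POSIXct("2013-08-12 13:54:59", tz = "UTC")),
                   13L)
  expect_identical(hour_of_day(as.POSIXct("2013-08-12 00:00:00", tz = "UTC")),
                   0L)
  expect_identical(hour_of_day(as.POSIXct("2013-08-12 23:58:00", tz = "UTC")),
                   0L)
  naive <- t0_utc
  attr(naive, "tzone") <- NULL
  expect_error(hour_of_day(naive), "timezone")
})
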