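wp <- toy_workplace()

test_that("in-range decision is a closed 1-km ball with ordered tie-break", {
  # points 0.5, exactly 1.0, and 1.5 km due north of the workplace
  km_per_deg <- 6371.0 * pi / 180
  lat <- wp$lat + c(0.5, 1.0, 1.5) / km_per_deg
  r <- fix_in_range(lat, rep(wp$lon, 3), wp)
  expect_equal(r$in_range, c(TRUE, TRUE, FALSE))
  expect_equal(r$dist_km, c(0.5, 1.0, 1.5), tolerance = 1e-9)
  # two workplaces at identical positions: first registered wins
  wp2 <- rbind(wp, data.frame(workplace_id = "w2", lat = wp$lat,
                              lon = wp$lon))
  expect_equal(fix_in_range(wp$lat, wp$lon, wp2)$workplace_id, "w1")
  expect_error(fix_in_range(0, 0, wp[0, ]), "workplace")
  expect_error(fix_in_range(0, 0, rbind(wp2, wp2, wp2)), "5 workplaces")
})

test_that("a full workday trace yields one session with retroactive start", {
  # in range 08:50 through 18:20 every 10 min, out of range before/after
  minutes <- seq(6 * 60, 21 * 60, by = 10)
  at_work <- minutes >= (8 * 60 + 50) & minutes <= (18 * 60 + 20)
  s <- detect_sessions(make_trace(minutes, at_work), wp)
  expect_equal(nrow(s), 1L)
  expect_equal(format(s$start, "%H:%M"), "08:50")
  expect_equal(format(s$end, "%H:%M"), "18:20")
  expect_equal(s$duration_min, 570)
  expect_false(s$open_at_end)
})

test_that("short in-range runs never open and short excursions never split", {
  # 20-minute presence: below the 30-minute confirmation window
  s <- detect_sessions(make_trace(c(0, 10, 20), c(TRUE, TRUE, TRUE)), wp)
  expect_equal(nrow(s), 0L)
  # 08:00-12:00 in, 12:10-12:20 out (20-min excursion), 12:30-17:00 in
  minutes <- seq(8 * 60, 17 * 60, by = 10)
  at_work <- !(minutes %in% c(12 * 60 + 10, 12 * 60 + 20))
  s <- detect_sessions(make_trace(minutes, at_work), wp)
  expect_equal(nrow(s), 1L)
  expect_equal(format(s$start, "%H:%M"), "08:00")
  expect_equal(format(s$end, "%H:%M"), "17:00")
  # an out-of-range run spanning >= 30 min closes at the last in fix
  at_work2 <- minutes < 12 * 60 | minutes > 12 * 60 + 40
  s2 <- detect_sessions(make_trace(minutes, at_work2), wp)
  expect_equal(nrow(s2), 2L)
  expect_equal(format(s2$end[1], "%H:%M"), "11:50")
  expect_equal(format(s2$start[2], "%H:%M"), "12:50")
})

test_that("missing-data gaps close an open session conservatively", {
  # in range 08:00-10:00, then silence until 11:00, then in range again
  minutes <- c(seq(8 * 60, 10 * 60, by = 10), seq(11 * 60, 12 * 60, by = 10))
  s <- detect_sessions(make_trace(minutes, rep(TRUE, length(minutes))), wp)
  expect_equal(nrow(s), 2L)
  expect_equal(format(s$end[1], "%H:%M"), "10:00")
  expect_equal(format(s$start[2], "%H:%M"), "11:00")
  expect_true(s$open_at_end[2])  # trace ends while in range
})

test_that("unsorted and empty traces are handled per contract", {
  tr <- make_trace(c(0, 20, 10), rep(TRUE, 3))
  expect_error(detect_sessions(tr, wp), "increasing")
  expect_equal(nrow(detect_sessions(tr[0, ], wp)), 0L)
})

test_that("sessions are disjoint and ordered on random traces", {
  set.seed(202)
  for (rep in 1:25) {
    n <- sample(30:120, 1)
    minutes <- cumsum(sample(c(10, 10, 10, 20, 40), n, replace = TRUE))
    at_work <- runif(n) < 0.6
    s <- detect_sessions(make_trace(minutes, at_work), wp)
    if (nrow(s) > 1) {
      expect_true(all(diff(as.numeric(s$start)) > 0))
      expect_true(all(as.numeric(s$start[-1]) > as.numeric(s$end[-nrow(s)])))
    }
    expect_true(all(s$end > s$start))
  }
})

test_that("subsampling that preserves run structure preserves sessions", {
  minutes <- seq(0, 16 * 60, by = 10)
  at_work <- minutes >= 500 & minutes <= 900
  full <- make_trace(minutes, at_work)
  # drop every other interior fix of each run; run boundaries retained
  runs <- rle(at_work)
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  keep <- rep(FALSE, length(minutes))
  for (r in seq_along(starts)) {
    idx <- starts[r]:ends[r]
    keep[idx[c(TRUE, FALSE)]] <- TRUE
    keep[c(starts[r], ends[r])] <- TRUE
  }
  sub <- full[keep, ]
  s_full <- detect_sessions(full, wp)
  s_sub <- detect_sessions(sub, wp)
  expect_equal(s_full$start, s_sub$start)
  expect_equal(s_full$end, s_sub$end)
  d_full <- daily_work_hours(s_full)
  d_sub <- daily_work_hours(s_sub)
  expect_equal(d_full$total_hours, d_sub$total_hours)
})

test_that("noise-free generated traces round-trip through detection", {
  g <- trace_geometry(noise_sd_m = 0, dropout = 0)
  tr <- generate_trace("u9", as.Date("2018-09-03"), geometry = g)
  s <- detect_sessions(tr, data.frame(workplace_id = "w1", lat = g$work_lat,
                                      lon = g$work_lon))
  expect_equal(nrow(s), 1L)
  expect_equal(format(s$start, "%H:%M"), "08:50")
  expect_equal(format(s$end, "%H:%M"), "18:20")
  # total dropout yields an empty trace
  g2 <- trace_geometry(dropout = 1)
  expect_equal(nrow(generate_trace("u9", as.Date("2018-09-03"),
                                   geometry = g2)), 0L)
})

test_that("noisy traces recover session boundaries within one interval", {
  g <- trace_geometry(noise_sd_m = 50, dropout = 0,
                      home_lat = 25.13, home_lon = 121.535)  # ~10 km away
  wp_g <- data.frame(workplace_id = "w1", lat = g$work_lat, lon = g$work_lon)
  set.seed(77)
  worst <- 0
  for (k in 1:100) {
    tr <- generate_trace("u1", as.Date("2018-09-03"), geometry = g)
    s <- detect_sessions(tr, wp_g)
    expect_equal(nrow(s), 1L)
    start_err <- abs(as.numeric(difftime(
      s$start, as.POSIXct("2018-09-03 08:50", tz = "Asia/Taipei"),
      units = "mins")))
    end_err <- abs(as.numeric(difftime(
      s$end, as.POSIXct("2018-09-03 18:20", tz = "Asia/Taipei"),
      units = "mins")))
    worst <- max(worst, start_err, end_err)
  }
  expect_lte(worst, g$fix_interval_min)
})

test_that("daily hours split at local midnight and overtime is signed", {
  tz <- "Asia/Taipei"
  s <- data.frame(user_id = "u1",
                  start = as.POSIXct(c("2018-09-03 08:50",
                                       "2018-09-04 22:00"), tz = tz),
                  end = as.POSIXct(c("2018-09-03 18:20",
                                     "2018-09-05 02:00"), tz = tz))
  d <- daily_work_hours(s, scheduled_hours = 8,
                        dates = as.Date(c("2018-09-03", "2018-09-04",
                                          "2018-09-05", "2018-09-06")))
  expect_equal(d$total_hours, c(9.5, 2, 2, 0))
  expect_equal(d$overtime_hours, c(1.5, -6, -6, -8))
  expect_equal(overtime_hours(10, 8), 2)
  expect_equal(overtime_hours(8, 8), 0)
  expect_equal(overtime_hours(6, 8), -2)
  expect_error(overtime_hours(-1, 8), "non-negative")
})
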