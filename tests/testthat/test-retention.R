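reg <- as.Date("2018-09-01")

test_that("successful installation requires an upload inside the window", {
  expect_true(successful_installation(reg, reg))
  expect_true(successful_installation(reg + 27, reg))
  expect_false(successful_installation(reg + 28, reg))
  expect_false(successful_installation(reg + 40, reg))
  expect_false(successful_installation(as.Date(character(0)), reg))
  expect_error(successful_installation(reg - 1, reg), "precede")
})

test_that("churn dates follow the gap rule under the last-upload anchor", {
  p <- retention_params(churn_anchor = "last_upload")
  expect_equal(unlist(churn_time(reg + 0:9, reg, reg + 200, p)),
               c(duration_days = 9, event = 1))
  # uploads continue to 10 days before cutoff: silence too short, censored
  expect_equal(unlist(churn_time(reg + 0:190, reg, reg + 200, p)),
               c(duration_days = 200, event = 0))
  # single upload at registration, then permanent silence
  expect_equal(unlist(churn_time(reg, reg, reg + 200, p)),
               c(duration_days = 0, event = 1))
  # boundary: a 28-day horizon with a single day-0 upload is just enough
  expect_equal(unlist(churn_time(reg, reg, reg + 28, p))[["event"]], 1)
  expect_equal(unlist(churn_time(reg, reg, reg + 27, p))[["event"]], 0)
})

test_that("the gap-start anchor shifts event durations by one day", {
  p_gap <- retention_params()  # gap_start is the default
  p_last <- retention_params(churn_anchor = "last_upload")
  set.seed(31)
  for (k in 1:50) {
    horizon <- sample(40:300, 1)
    days <- random_upload_days(horizon)
    a <- churn_time(reg + days, reg, reg + horizon, p_gap)
    b <- churn_time(reg + days, reg, reg + horizon, p_last)
    expect_equal(a$event, b$event)
    expect_equal(a$duration_days, b$duration_days + a$event)
  }
})

test_that("re-entry after a qualifying silence is ignored", {
  p <- retention_params(churn_anchor = "last_upload")
  days <- c(0:5, 50:60)
  expect_equal(unlist(churn_time(reg + days, reg, reg + 300, p)),
               c(duration_days = 5, event = 1))
})

test_that("churn scan agrees with the brute-force day-by-day oracle", {
  set.seed(7)
  for (anchor in c("gap_start", "last_upload")) {
    p <- retention_params(churn_anchor = anchor)
    for (k in 1:300) {
      horizon <- sample(29:250, 1)
      days <- random_upload_days(horizon)
      got <- churn_time(reg + days, reg, reg + horizon, p)
      want <- oracle_churn(days, horizon, 28, anchor)
      expect_identical(got$duration_days, want$duration_days)
      expect_identical(got$event, want$event)
    }
  }
})

test_that("extending the cutoff is monotone in the observed churn status", {
  p <- retention_params()
  set.seed(13)
  for (k in 1:80) {
    h1 <- sample(29:150, 1)
    h2 <- h1 + sample(1:150, 1)
    days <- random_upload_days(h2)
    a <- churn_time(reg + days[days <= h1], reg, reg + h1, p)
    b <- churn_time(reg + days, reg, reg + h2, p)
    expect_gte(b$event, a$event)               # 0 can flip to 1, never back
    if (a$event == 1) {
      # an observed churn is final: extending observation changes nothing
      expect_equal(b$duration_days, a$duration_days)
    } else if (b$event == 0) {
      # still censored: duration grows with the horizon
      expect_equal(b$duration_days, h2)
    } else {
      # newly revealed churn: its silence must have straddled the old
      # cutoff (otherwise it would already have been visible), so the
      # churn date lies within gap_days of the old horizon
      expect_gt(b$duration_days, h1 - 28)
      expect_lte(b$duration_days, h2)
    }
  }
})

test_that("event flags are consistent with the silence they claim", {
  p <- retention_params(churn_anchor = "last_upload")
  set.seed(19)
  for (k in 1:60) {
    horizon <- sample(29:250, 1)
    days <- random_upload_days(horizon)
    r <- churn_time(reg + days, reg, reg + horizon, p)
    after <- days[days > r$duration_days]
    nxt <- if (length(after)) min(after) else horizon
    if (r$event == 1) {
      expect_gte(nxt - r$duration_days, 28)
    } else {
      # censored: no 28-day silence anywhere from registration to cutoff
      expect_true(all(diff(unique(c(0, days, horizon))) < 28))
    }
  }
})

test_that("exclusions drop missing demographics first, then failed installs", {
  fx <- enrollment_fixture(n_complete = 20, n_missing = 5)
  # make three complete users miss the install window
  late <- fx$users$user_id[1:3]
  fx$uploads$time[fx$uploads$user_id %in% late] <-
    fx$users$registration[1:3] + 40
  res <- apply_exclusions(fx$users, fx$uploads)
  expect_equal(unname(res$counts),
               c(25, 5, 3, 17))
  expect_equal(sum(res$excluded$reason == "missing_demographics"), 5)
  expect_equal(sum(res$excluded$reason == "failed_installation"), 3)
  expect_equal(nrow(res$included), 17)
  # all-complete cohort: nothing excluded
  fx2 <- enrollment_fixture(n_complete = 10, n_missing = 0)
  expect_equal(nrow(apply_exclusions(fx2$users, fx2$uploads)$included), 10)
})

test_that("the retention table has two ordered records per user", {
  fx <- enrollment_fixture(n_complete = 6, n_missing = 0)
  # give users passive uploads only; active stream must still get a record
  rt <- build_retention_table(fx$users, fx$uploads,
                              window = max(fx$users$registration) + 100)
  expect_equal(nrow(rt), 12L)
  expect_equal(rt$stream, rep(c("active", "passive"), 6))
  expect_equal(rt$user_id, rep(sort(fx$users$user_id), each = 2))
  # no active uploads at all: the silence clock runs from registration
  act <- rt[rt$stream == "active", ]
  expect_true(all(act$event == 1))
  expect_true(all(act$duration_days == 1))  # gap_start anchor, day-0 contact
  # empty cohort
  empty <- build_retention_table(fx$users[0, ], fx$uploads[0, ],
                                 window = reg + 10)
  expect_equal(nrow(empty), 0L)
})
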