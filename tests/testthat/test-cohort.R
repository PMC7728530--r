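test_that("hazard calibration inverts week/month survival in closed form", {
  expect_equal(unname(calibrate_hazards(1, 1)), c(0, 0))
  expect_equal(unname(calibrate_hazards(exp(-7), exp(-28))), c(1, 1))
  l <- calibrate_hazards(0.467, 0.273)
  expect_equal(exp(-l[["lambda1"]] * 7), 0.467, tolerance = 1e-12)
  expect_equal(exp(-l[["lambda1"]] * 7 - l[["lambda2"]] * 21), 0.273,
               tolerance = 1e-12)
  expect_error(calibrate_hazards(0.3, 0.5), "s_month")
})

test_that("piecewise-exponential sampling matches its survival function", {
  set.seed(67)
  rates <- c(0.1, 0.02, 0.02)
  t <- sample_piecewise_exp(1e5, rates)
  for (at in c(3, 7, 14, 28, 60)) {
    expect_equal(mean(t > at), piecewise_exp_survival(at, rates),
                 tolerance = 0.02)
  }
  expect_true(all(sample_piecewise_exp(100, c(0, 0, 0)) == Inf))
  expect_error(sample_piecewise_exp(10, c(-1, 0, 0)))
})

test_that("cohort generation is deterministic under a fixed seed", {
  a <- generate_cohort(cohort_config(n_users = 40, seed = 71, trace_days = 1))
  b <- generate_cohort(cohort_config(n_users = 40, seed = 71, trace_days = 1))
  expect_identical(a, b)
  c_ <- generate_cohort(cohort_config(n_users = 40, seed = 72))
  expect_false(identical(a$uploads, c_$uploads))
})

test_that("zero hazards mean nobody churns and uploads never stop", {
  zero <- list(android = c(0, 0, 0), ios = c(0, 0, 0))
  cfg <- cohort_config(n_users = 25, seed = 3,
                       churn_hazards = list(passive = zero, active = zero))
  coh <- generate_cohort(cfg)
  expect_true(all(is.na(coh$ground_truth$true_churn_day)))
  rt <- build_retention_table(coh)
  expect_true(all(rt$event == 0))
  horizon <- as.integer(cfg$study_cutoff -
                          coh$users$registration[match(rt$user_id,
                                                       coh$users$user_id)])
  expect_equal(rt$duration_days, horizon)
  # passive uploads present every single day up to the cutoff
  up <- coh$uploads[coh$uploads$stream == "passive", ]
  cnt <- table(up$user_id)
  expect_equal(as.integer(cnt),
               as.integer(cfg$study_cutoff - coh$users$registration) + 1L)
})

test_that("covariate margins honour the configured mix exactly", {
  cfg <- cohort_config(n_users = 342, seed = 9)
  coh <- generate_cohort(cfg)
  occ <- table(coh$users$occupation)
  expect_equal(occ[["resident_physician"]], 128)
  expect_equal(sum(occ[c("resident_physician", "visiting_staff",
                         "medical_student", "nurse")]), 286)
  expect_equal(sum(coh$users$platform == "android"), 109)  # round(0.318*342)
  expect_true(all(coh$users$age >= 20 & coh$users$age <= 59))
  expect_true(all(coh$users$registration >= cfg$registration_window[1] &
                    coh$users$registration <= cfg$registration_window[2]))
})

test_that("the retention pipeline recovers ground-truth churn days", {
  cfg <- cohort_config(n_users = 150, seed = 101)
  coh <- generate_cohort(cfg)
  rt <- build_retention_table(
    coh, params = retention_params(churn_anchor = "last_upload"))
  m <- merge(rt, coh$ground_truth, by = c("user_id", "stream"))
  horizon <- as.integer(cfg$study_cutoff -
                          coh$users$registration[match(m$user_id,
                                                       coh$users$user_id)])
  # a churn is observable iff the full 28-day silence fits before cutoff
  observable <- !is.na(m$true_churn_day) & (horizon - m$true_churn_day) >= 28
  expect_true(all(m$event[observable] == 1))
  expect_equal(m$duration_days[observable], m$true_churn_day[observable])
  expect_true(all(m$event[!observable] == 0))
  expect_equal(m$duration_days[!observable], horizon[!observable])
})

test_that("generated KM curves converge to the configured survival", {
  cfg <- cohort_config(
    n_users = 10000, seed = 103,
    churn_hazards = list(passive = uniform_hazards(0.467, 0.273),
                         active = uniform_hazards(0.222, 0.034)))
  coh <- generate_cohort(cfg)
  rt <- build_retention_table(coh)
  for (s in c("passive", "active")) {
    d <- rt[rt$stream == s, ]
    km <- kaplan_meier(d$duration_days, d$event)
    truth <- if (s == "passive") c(0.467, 0.273) else c(0.222, 0.034)
    expect_lt(abs(survival_at(km, 7) - truth[1]), 0.02)
    expect_lt(abs(survival_at(km, 28) - truth[2]), 0.02)
  }
})

test_that("monthly survey cadence forces churn at the first month gap", {
  zero <- list(android = c(0, 0, 0), ios = c(0, 0, 0))
  cfg <- cohort_config(n_users = 30, seed = 107, active_cadence = "monthly",
                       churn_hazards = list(passive = zero, active = zero))
  coh <- generate_cohort(cfg)
  act <- coh$uploads[coh$uploads$stream == "active", ]
  expect_true(all(format(act$time, "%d") == "01"))
  rt <- build_retention_table(coh)
  # every month-to-month gap is >= 28 days, so the silence rule fires for
  # everyone even though nobody truly churned: the documented artifact
  expect_true(all(rt$event[rt$stream == "active"] == 1))
  expect_true(all(rt$duration_days[rt$stream == "active"] <= 32))
  expect_true(all(rt$event[rt$stream == "passive"] == 0))
})

test_that("the occupation hazard multiplier acts on residents only", {
  cfg <- cohort_config(
    n_users = 6000, seed = 109,
    churn_hazards = list(passive = uniform_hazards(0.6, 0.4),
                         active = uniform_hazards(0.6, 0.4)),
    occupation_hr = c(passive = 1, active = 0.25))
  coh <- generate_cohort(cfg)
  gt <- merge(coh$ground_truth, coh$users[, c("user_id", "occupation")])
  res <- gt$occupation == "resident_physician"
  act <- gt$stream == "active"
  # passive: residents indistinguishable; active: residents churn ~4x slower
  p_res <- mean(gt$true_time[act & res] > 14)
  p_oth <- mean(gt$true_time[act & !res] > 14)
  expect_gt(p_res, p_oth + 0.1)
  expect_lt(abs(mean(gt$true_time[!act & res] > 14) -
                  mean(gt$true_time[!act & !res] > 14)), 0.05)
})
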