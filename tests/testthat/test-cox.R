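test_that("a known hazard ratio is recovered on a large simulated sample", {
  set.seed(41)
  n <- 5000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(log(2) * x))
  fit <- cox_ph(t, rep(1L, n), x)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit) - log(2)), 3 * fit$se)
})

test_that("degenerate designs raise the contracted errors", {
  set.seed(43)
  t <- rexp(30); st <- rep(1L, 30); x <- rnorm(30)
  expect_error(cox_ph(t, st, cbind(a = x, b = x)), "singular")
  expect_error(cox_ph(t, st, rep(1, 30)), "constant")
  expect_error(cox_ph(t, rep(0L, 30), x), "no events")
  # complete separation: all x=1 events strictly precede all x=0 events
  xs <- rep(c(1, 0), each = 6)
  ts <- c(1:6, 101:106)
  expect_error(cox_ph(ts, rep(1L, 12), xs), "separation|monotone")
})

test_that("Efron and Breslow coincide exactly in the absence of ties", {
  set.seed(47)
  d <- random_surv_data(n = 50, p = 2, ties = FALSE)
  fe <- cox_ph(d$time, d$status, d$x, ties = "efron", tol = 1e-12)
  fb <- cox_ph(d$time, d$status, d$x, ties = "breslow", tol = 1e-12)
  expect_equal(coef(fe), coef(fb), tolerance = 1e-10)
  expect_equal(fe$se, fb$se, tolerance = 1e-10)
})

test_that("the score test at zero equals the log-rank chi-square (no ties)", {
  set.seed(53)
  for (k in 1:30) {
    d <- random_surv_data(n = sample(20:60, 1), ties = FALSE)
    g <- rbinom(length(d$time), 1, 0.5)
    if (length(unique(g)) < 2) next
    lr <- log_rank(d$time, d$status, g)
    fit <- cox_ph(d$time, d$status, g, tol = 1e-12)
    expect_equal(fit$score_test$statistic, lr$chi_square, tolerance = 1e-8)
  }
})

test_that("coefficients match the survival package, with and without ties", {
  skip_if_not_installed("survival")
  set.seed(59)
  ctrl <- suppressWarnings(survival::coxph.control(eps = 1e-12, iter.max = 50))
  for (k in 1:60) {
    d <- random_surv_data(n = sample(20:60, 1), p = sample(1:2, 1),
                          ties = k %% 2 == 0)
    for (ties in c("efron", "breslow")) {
      fit <- cox_ph(d$time, d$status, d$x, ties = ties, tol = 1e-12)
      or <- suppressWarnings(
        survival::coxph(survival::Surv(d$time, d$status) ~ d$x,
                        ties = ties, control = ctrl))
      expect_equal(unname(coef(fit)), unname(coef(or)), tolerance = 1e-6)
      expect_equal(unname(fit$se),
                   unname(sqrt(diag(stats::vcov(or)))), tolerance = 1e-6)
      expect_equal(fit$loglik[["final"]], or$loglik[2], tolerance = 1e-8)
    }
  }
})

test_that("Wald intervals bracket the hazard ratio and methods behave", {
  set.seed(61)
  d <- random_surv_data(n = 80, p = 2)
  fit <- cox_ph(d$time, d$status, d$x)
  expect_true(all(fit$ci_lower < fit$hazard_ratio &
                    fit$hazard_ratio < fit$ci_upper))
  expect_equal(exp(confint(fit))[, 1], fit$ci_lower)
  expect_equal(unname(exp(coef(fit))), unname(fit$hazard_ratio))
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  # martingale residuals sum to ~0 and expected counts total the events
  r <- residuals(fit)
  expect_lt(abs(sum(r)), 1e-8)
  expect_equal(sum(predict(fit, type = "expected")), fit$n_events,
               tolerance = 1e-8)
  # linear predictor is centred; risk = exp(lp)
  lp <- predict(fit, type = "lp")
  expect_equal(predict(fit, type = "risk"), exp(lp))
  expect_lt(abs(mean(lp)), 10)
  expect_output(print(fit), "Cox")
  expect_output(print(summary(fit)), "score test")
})
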