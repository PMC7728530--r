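#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric estimate of the survival function from right-censored
#' durations, with Greenwood variance. At each distinct event time
#' \eqn{t_i} with \eqn{d_i} events among \eqn{n_i} subjects at risk, the
#' survival estimate is \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)};
#' subjects censored at \eqn{t_i} are still at risk at \eqn{t_i}.
#' Greenwood's formula gives
#' \eqn{\widehat{Var}\,S(t) = S(t)^2 \sum_{t_i \le t} d_i /(n_i (n_i - d_i))}.
#'
#' @param time Non-negative numeric vector of durations.
#' @param status Event indicator: 1 (or `TRUE`) = event observed,
#'   0 = right-censored.
#' @return An object of class `"km_fit"`: a list with `time` (distinct
#'   event times), `n_risk`, `n_event`, `surv`, `std_err` (Greenwood SE
#'   of S), `n`, `n_events`, `max_time`.
#' @examples
#' fit <- kaplan_meier(c(1, 2, 3, 4), c(1, 0, 1, 0))
#' fit$surv
#' survival_at(fit, 3)
#' @seealso [survival_at()], [log_rank()], [cox_ph()]
#' @export
kaplan_meier <- function(time, status) {
  status <- as.integer(status)
  if (length(time) == 0L) {
    stop("kaplan_meier needs at least one record", call. = FALSE)
  }
  if (length(time) != length(status) || anyNA(time) || anyNA(status)) {
    stop("time and status must be equal-length and non-missing",
         call. = FALSE)
  }
  if (any(time < 0) || !all(status %in% c(0L, 1L))) {
    stop("time must be >= 0 and status in {0, 1}", call. = FALSE)
  }
  ev <- sort(unique(time[status == 1L]))
  if (length(ev) == 0L) {
    out <- list(time = numeric(0), n_risk = integer(0), n_event = integer(0),
                surv = numeric(0), std_err = numeric(0),
                n = length(time), n_events = 0L, max_time = max(time))
    return(structure(out, class = "km_fit"))
  }
  ts <- sort(time)
  # subjects at risk at t: those with duration >= t
  n_risk <- length(time) - findInterval(ev, ts, left.open = TRUE)
  n_event <- vapply(ev, function(t) sum(time == t & status == 1L), integer(1))
  frac <- 1 - n_event / n_risk
  surv <- cumprod(frac)
  gw_term <- n_event / (n_risk * (n_risk - n_event))
  gw_term[n_risk == n_event] <- NA_real_  # S hits 0; variance undefined
  var_s <- surv^2 * cumsum(gw_term)
  var_s[surv == 0] <- 0
  structure(list(time = ev,
                 n_risk = as.integer(n_risk),
                 n_event = as.integer(n_event),
                 surv = surv,
                 std_err = sqrt(var_s),
                 n = length(time),
                 n_events = sum(status),
                 max_time = max(time)),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function evaluation: `survival_at(fit, t)` is
#' the estimated probability of surviving beyond `t`. Before the first
#' event the curve is 1; beyond the last event time the last value is
#' carried forward.
#'
#' @param fit A `"km_fit"` object from [kaplan_meier()].
#' @param t Non-negative numeric vector of evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  if (anyNA(t) || any(t < 0)) {
    stop("evaluation times must be >= 0", call. = FALSE)
  }
  idx <- findInterval(t, fit$time)
  c(1, fit$surv)[idx + 1L]
}

#' @export
print.km_fit <- function(x, digits = 4, ...) {
  cat("Kaplan-Meier estimate:", x$n, "subjects,", x$n_events, "events\n")
  med <- km_quantile(x, 0.5)
  cat("Median survival time:",
      if (is.na(med)) "not reached" else format(med), "\n")
  invisible(x)
}

# smallest event time with S(t) <= 1 - p (NA if never reached)
km_quantile <- function(fit, p) {
  hit <- which(fit$surv <= 1 - p)
  if (length(hit) == 0L) NA_real_ else fit$time[hit[1L]]
}

#' @export
summary.km_fit <- function(object, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(time = object$time,
                    n_risk = object$n_risk,
                    n_event = object$n_event,
                    survival = object$surv,
                    std_err = object$std_err,
                    lower = pmax(0, object$surv - z * object$std_err),
                    upper = pmin(1, object$surv + z * object$std_err))
  structure(list(table = tab, n = object$n, n_events = object$n_events,
                 conf_level = conf_level),
            class = "summary.km_fit")
}

#' @export
print.summary.km_fit <- function(x, digits = 4, ...) {
  cat("Kaplan-Meier estimate (", x$n, " subjects, ", x$n_events,
      " events, ", format(100 * x$conf_level), "% CI)\n", sep = "")
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Plot a Kaplan-Meier curve
#'
#' @param x A `"km_fit"` object.
#' @param conf_int Draw pointwise Greenwood confidence bands. Default
#'   `TRUE`.
#' @param conf_level Band level. Default 0.95.
#' @param xlab,ylab,col,lty,... Usual graphical arguments.
#' @param add Add to an existing plot instead of opening a new one.
#' @return Invisibly, `x`.
#' @export
plot.km_fit <- function(x, conf_int = TRUE, conf_level = 0.95,
                        xlab = "days since registration",
                        ylab = "retention probability",
                        col = 1, lty = 1, add = FALSE, ...) {
  tt <- c(0, x$time, x$max_time)
  ss <- c(1, x$surv, x$surv[length(x$surv)])
  if (length(x$time) == 0L) ss <- c(1, 1)
  if (!add) {
    plot(tt, ss, type = "n", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  }
  graphics::lines(tt, ss, type = "s", col = col, lty = lty)
  if (conf_int && length(x$time)) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    lo <- pmax(0, x$surv - z * x$std_err)
    hi <- pmin(1, x$surv + z * x$std_err)
    graphics::lines(c(0, x$time, x$max_time), c(1, lo, lo[length(lo)]),
                    type = "s", col = col, lty = 3)
    graphics::lines(c(0, x$time, x$max_time), c(1, hi, hi[length(hi)]),
                    type = "s", col = col, lty = 3)
  }
  invisible(x)
}

#' @rdname plot.km_fit
#' @export
lines.km_fit <- function(x, conf_int = FALSE, col = 1, lty = 1, ...) {
  plot.km_fit(x, conf_int = conf_int, col = col, lty = lty, add = TRUE, ...)
}
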