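#' Two-sample log-rank test
#'
#' Compares the survival curves of two groups via the observed-minus-
#' expected number of events accumulated over the pooled distinct event
#' times, with the hypergeometric variance. At pooled event time
#' \eqn{t_j} with \eqn{d_j} events among \eqn{n_j} at risk
#' (\eqn{n_{1j}} in group 1), group 1 contributes expectation
#' \eqn{d_j n_{1j}/n_j} and variance
#' \eqn{d_j (n_{1j}/n_j)(1 - n_{1j}/n_j)(n_j - d_j)/(n_j - 1)}.
#' The statistic \eqn{(O_1 - E_1)^2 / V} is referred to a chi-square
#' distribution with 1 degree of freedom; the p-value is two-sided.
#'
#' @param time Numeric vector of durations (both groups pooled).
#' @param status Event indicator (1 = event, 0 = censored).
#' @param group Two-level grouping vector (factor, character or
#'   numeric); both levels must be present.
#' @return An object of class `"logrank_test"`: `chi_square`, `df`,
#'   `p_value`, `observed`, `expected` (named per group), `variance`,
#'   and the group labels.
#' @examples
#' lr <- log_rank(c(1, 4, 6, 2, 3, 5), c(1, 1, 0, 1, 0, 1),
#'                c("a", "a", "a", "b", "b", "b"))
#' lr$chi_square
#' @export
log_rank <- function(time, status, group) {
  status <- as.integer(status)
  group <- as.factor(group)
  if (length(time) != length(status) || length(time) != length(group)) {
    stop("time, status and group must have equal length", call. = FALSE)
  }
  if (nlevels(droplevels(group)) != 2L) {
    stop("log_rank compares exactly two non-empty groups", call. = FALSE)
  }
  group <- droplevels(group)
  if (sum(status) == 0L) {
    stop("no events in either group", call. = FALSE)
  }
  g1 <- group == levels(group)[1L]
  ev <- sort(unique(time[status == 1L]))
  o1 <- e1 <- v <- 0
  for (t in ev) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(time == t & status == 1L)
    d1 <- sum(time == t & status == 1L & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1L) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  obs <- c(o1, sum(status) - o1)
  exp_ <- c(e1, sum(status) - e1)
  names(obs) <- names(exp_) <- levels(group)
  chi <- if (v > 0) (o1 - e1)^2 / v else 0
  structure(list(chi_square = chi,
                 df = 1L,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 observed = obs,
                 expected = exp_,
                 variance = v,
                 groups = levels(group)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, digits = 4, ...) {
  cat("Two-sample log-rank test\n")
  tab <- data.frame(group = x$groups,
                    observed = x$observed,
                    expected = signif(x$expected, digits))
  print(tab, row.names = FALSE)
  cat("chi-square =", format(signif(x$chi_square, digits)),
      "on", x$df, "df, p =", format.pval(x$p_value, digits = digits), "\n")
  invisible(x)
}
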