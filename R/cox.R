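#' Cox proportional-hazards regression
#'
#' Fits the Cox model by maximising the log partial likelihood with
#' Newton-Raphson iteration, written from first principles. Tied event
#' times are handled by the Efron approximation (default) or the
#' Breslow approximation; the two coincide exactly when no ties exist.
#' Standard errors are Wald, from the inverse of the observed
#' information at the maximum; 95% confidence intervals are
#' \eqn{\exp(\beta \pm z_{0.975}\, se)}. The score test evaluated at
#' \eqn{\beta = 0} is also returned (for a single binary covariate
#' without ties it equals the log-rank chi-square).
#'
#' @param time Numeric vector of durations.
#' @param status Event indicator (1 = event, 0 = censored); at least
#'   one event is required.
#' @param x Covariates: a numeric vector, a numeric matrix, or a data
#'   frame (factors are expanded to indicator columns). No covariate
#'   may be constant.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol Relative convergence tolerance on the log partial
#'   likelihood. Default 1e-9.
#' @param max_iter Maximum Newton-Raphson iterations. Default 100.
#' @return An object of class `"cox_fit"`: coefficients, `var`
#'   (variance-covariance matrix), `se`, `hazard_ratio`, `ci_lower`,
#'   `ci_upper`, `z`, `p_value`, `loglik` (null and final), `score_test`
#'   (statistic, df, p at beta = 0), `iter`, `converged`, `ties`, `n`,
#'   `n_events`, and the data needed by the methods.
#' @examples
#' set.seed(1)
#' x <- rbinom(80, 1, 0.5)
#' t <- rexp(80, 0.1 * exp(log(2) * x))
#' fit <- cox_ph(t, rep(1, 80), x)
#' coef(fit)
#' summary(fit)
#' @seealso [kaplan_meier()], [log_rank()], [fit_retention_models()]
#' @export
cox_ph <- function(time, status, x, ties = c("efron", "breslow"),
                   tol = 1e-9, max_iter = 100) {
  ties <- match.arg(ties)
  status <- as.integer(status)
  X <- cox_model_matrix(x)
  n <- length(time)
  if (nrow(X) != n || length(status) != n) {
    stop("time, status and x must agree in length", call. = FALSE)
  }
  if (anyNA(time) || anyNA(status) || anyNA(X)) {
    stop("missing values are not supported", call. = FALSE)
  }
  if (sum(status) < 1L) {
    stop("no events: the partial likelihood is undefined", call. = FALSE)
  }
  sdx <- apply(X, 2, stats::sd)
  if (any(sdx == 0)) {
    stop("covariate '", colnames(X)[which(sdx == 0)[1L]],
         "' is constant; the model is degenerate", call. = FALSE)
  }
  means <- colMeans(X)
  Xc <- sweep(X, 2, means)
  prep <- cox_prepare(time, status, Xc)
  p <- ncol(Xc)

  beta <- rep(0, p)
  t0 <- cox_terms(beta, prep, ties)
  loglik_null <- t0$ll
  info0 <- t0$info
  score0 <- t0$score
  score_stat <- tryCatch(drop(crossprod(score0, solve(info0, score0))),
                         error = function(e) NA_real_)

  ll <- t0$ll
  cur <- t0
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    delta <- tryCatch(solve(cur$info, cur$score), error = function(e) {
      stop("information matrix is singular (collinear covariates?)",
           call. = FALSE)
    })
    step <- 1
    repeat {
      beta_new <- beta + step * delta
      new <- cox_terms(beta_new, prep, ties)
      if (is.finite(new$ll) && new$ll >= ll - 1e-12) break
      step <- step / 2
      if (step < 2^-20) break
    }
    if (any(abs(beta_new) * sdx > 30)) {
      stop("partial likelihood appears monotone (complete separation); ",
           "coefficient diverging to infinity", call. = FALSE)
    }
    done <- abs(1 - new$ll / ll) < tol && iter > 1L ||
      abs(new$ll - ll) < tol * (abs(ll) + tol) && iter > 1L
    beta <- beta_new
    ll <- new$ll
    cur <- new
    if (done) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("Newton-Raphson did not converge in ", max_iter,
            " iterations; results are partial", call. = FALSE)
  }
  if (any(abs(beta) * sdx > 10)) {
    stop("partial likelihood appears monotone (complete separation); ",
         "coefficient diverging to infinity", call. = FALSE)
  }
  var <- solve(cur$info)
  se <- sqrt(diag(var))
  z <- beta / se
  zq <- stats::qnorm(0.975)
  names(beta) <- names(se) <- colnames(X)
  dimnames(var) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta,
                 var = var,
                 se = se,
                 hazard_ratio = exp(beta),
                 ci_lower = exp(beta - zq * se),
                 ci_upper = exp(beta + zq * se),
                 z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 loglik = c(null = loglik_null, final = ll),
                 score_test = list(statistic = score_stat, df = p,
                                   p_value = stats::pchisq(score_stat, p,
                                                           lower.tail = FALSE)),
                 iter = iter,
                 converged = converged,
                 ties = ties,
                 n = n,
                 n_events = sum(status),
                 means = means,
                 x = X,
                 time = time,
                 status = status),
            class = "cox_fit")
}

cox_model_matrix <- function(x) {
  if (is.data.frame(x)) {
    X <- stats::model.matrix(~ . , data = x)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  } else if (is.matrix(x)) {
    X <- x
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  } else {
    X <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, "x"))
  }
  storage.mode(X) <- "double"
  X
}

# Sort once (descending time) and pre-aggregate the tied-death sums.
cox_prepare <- function(time, status, X) {
  n <- length(time)
  p <- ncol(X)
  o <- order(time, decreasing = TRUE)
  tt <- time[o]
  ss <- status[o]
  XX <- X[o, , drop = FALSE]
  # packed upper-triangle cross products for the S2 cumulative sums
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  XXcross <- XX[, pairs[, 1], drop = FALSE] * XX[, pairs[, 2], drop = FALSE]
  dtimes <- unique(tt[ss == 1L])              # descending
  ta <- sort(time)
  m <- n - findInterval(dtimes, ta, left.open = TRUE)  # |risk set|
  ev <- which(ss == 1L)
  key <- factor(tt[ev], levels = dtimes)      # keep descending order
  dcount <- as.integer(table(key))
  eta_rows <- ev
  sumXD <- rowsum(XX[ev, , drop = FALSE], key, reorder = FALSE)
  sumXcrossD <- rowsum(XXcross[ev, , drop = FALSE], key, reorder = FALSE)
  list(n = n, p = p, tt = tt, ss = ss, XX = XX, XXcross = XXcross,
       pairs = pairs, dtimes = dtimes, m = m, ev = ev, key = key,
       dcount = dcount, sumXD = sumXD, sumXcrossD = sumXcrossD)
}

unpack_sym <- function(v, pairs, p) {
  S <- matrix(0, p, p)
  S[cbind(pairs[, 1], pairs[, 2])] <- v
  S[cbind(pairs[, 2], pairs[, 1])] <- v
  S
}

# Log partial likelihood, score vector and observed information.
cox_terms <- function(beta, prep, ties) {
  p <- prep$p
  eta <- drop(prep$XX %*% beta)
  eta <- eta - max(eta)  # guard against overflow; ll shifts cancel in U, I
  w <- exp(eta)
  cS0 <- cumsum(w)
  cS1 <- apply(prep$XX * w, 2, cumsum)
  cS1 <- matrix(cS1, ncol = p)
  cS2 <- apply(prep$XXcross * w, 2, cumsum)
  cS2 <- matrix(cS2, ncol = nrow(prep$pairs))
  # death-set aggregates at current beta
  wD <- rowsum(w[prep$ev], prep$key, reorder = FALSE)[, 1]
  wXD <- rowsum(prep$XX[prep$ev, , drop = FALSE] * w[prep$ev], prep$key,
                reorder = FALSE)
  wXcrossD <- rowsum(prep$XXcross[prep$ev, , drop = FALSE] * w[prep$ev],
                     prep$key, reorder = FALSE)
  sum_eta_D <- rowsum(eta[prep$ev], prep$key, reorder = FALSE)[, 1]

  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  for (j in seq_along(prep$dtimes)) {
    mj <- prep$m[j]
    d <- prep$dcount[j]
    S0 <- cS0[mj]
    S1 <- cS1[mj, ]
    S2 <- cS2[mj, ]
    ll <- ll + sum_eta_D[j]
    U <- U + prep$sumXD[j, ]
    fracs <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
    for (l in seq_len(d)) {
      f <- fracs[l]
      S0l <- S0 - f * wD[j]
      S1l <- S1 - f * wXD[j, ]
      S2l <- S2 - f * wXcrossD[j, ]
      mu <- S1l / S0l
      ll <- ll - log(S0l)
      U <- U - mu
      I <- I + unpack_sym(S2l, prep$pairs, p) / S0l - tcrossprod(mu)
    }
  }
  list(ll = as.numeric(ll), score = unname(U), info = I)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, ...) object$var

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik[["final"]], df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
nobs.cox_fit <- function(object, ...) object$n

#' @export
confint.cox_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients
  ci <- cbind(est - z * object$se, est + z * object$se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)),
                        "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.cox_fit <- function(x, digits = 4, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  tab <- data.frame(coef = x$coefficients,
                    `HR` = x$hazard_ratio,
                    `se(coef)` = x$se,
                    z = x$z,
                    p = x$p_value,
                    check.names = FALSE)
  print(signif(tab, digits))
  if (!x$converged) cat("WARNING: did not converge\n")
  invisible(x)
}

#' @export
summary.cox_fit <- function(object, ...) {
  tab <- data.frame(coef = object$coefficients,
                    hazard_ratio = object$hazard_ratio,
                    se = object$se,
                    ci_lower = object$ci_lower,
                    ci_upper = object$ci_upper,
                    z = object$z,
                    p_value = object$p_value)
  structure(list(table = tab, n = object$n, n_events = object$n_events,
                 loglik = object$loglik, score_test = object$score_test,
                 iter = object$iter, converged = object$converged,
                 ties = object$ties),
            class = "summary.cox_fit")
}

#' @export
print.summary.cox_fit <- function(x, digits = 4, ...) {
  cat("Cox proportional-hazards model (", x$ties, " approximation for ties)\n",
      sep = "")
  cat("n =", x$n, ", events =", x$n_events,
      ", Newton-Raphson iterations =", x$iter, "\n")
  print(signif(x$table, digits))
  lrt <- 2 * (x$loglik[["final"]] - x$loglik[["null"]])
  cat("Likelihood ratio test =", format(signif(lrt, digits)),
      "; score test =", format(signif(x$score_test$statistic, digits)),
      "on", x$score_test$df, "df\n")
  if (!x$converged) cat("WARNING: did not converge\n")
  invisible(x)
}

# Breslow estimator of the baseline cumulative hazard at the fitted
# coefficients (baseline = covariate means, since X was centered).
baseline_cumhaz <- function(object) {
  Xc <- sweep(object$x, 2, object$means)
  eta <- drop(Xc %*% object$coefficients)
  w <- exp(eta)
  ev <- sort(unique(object$time[object$status == 1L]))
  h <- vapply(ev, function(t) {
    sum(object$status == 1L & object$time == t) / sum(w[object$time >= t])
  }, numeric(1))
  list(time = ev, hazard = cumsum(h))
}

#' Predictions from a Cox fit
#'
#' @param object A `"cox_fit"` object.
#' @param newdata Optional covariate matrix/data frame/vector matching
#'   the fitted covariates; default: the training data.
#' @param type `"lp"` (linear predictor, centred at covariate means),
#'   `"risk"` (`exp(lp)`), or `"expected"` (expected number of events,
#'   training data only; Breslow baseline).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.cox_fit <- function(object, newdata = NULL,
                            type = c("lp", "risk", "expected"), ...) {
  type <- match.arg(type)
  if (type == "expected") {
    if (!is.null(newdata)) {
      stop("type = 'expected' is only available for the training data",
           call. = FALSE)
    }
    bh <- baseline_cumhaz(object)
    idx <- findInterval(object$time, bh$time)
    H0 <- c(0, bh$hazard)[idx + 1L]
    eta <- drop(sweep(object$x, 2, object$means) %*% object$coefficients)
    return(H0 * exp(eta))
  }
  X <- if (is.null(newdata)) object$x else cox_model_matrix(newdata)
  lp <- drop(sweep(X, 2, object$means) %*% object$coefficients)
  if (type == "risk") exp(lp) else lp
}

#' Martingale residuals of a Cox fit
#'
#' @param object A `"cox_fit"` object.
#' @param type Only `"martingale"` residuals are provided.
#' @param ... Unused.
#' @return Numeric vector, `status - expected`.
#' @export
residuals.cox_fit <- function(object, type = "martingale", ...) {
  type <- match.arg(type)
  object$status - predict(object, type = "expected")
}
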