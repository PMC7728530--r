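#' Fit the study's retention models on a retention table
#'
#' For each data stream (passive, active) this fits a Cox
#' proportional-hazards model on two binary factors -- operating system
#' (iOS vs Android) and occupation (resident physician vs others) --
#' computes Kaplan-Meier curves per stream and per stream-by-platform
#' stratum, and runs the log-rank comparisons: passive vs active
#' (pooled) and Android vs iOS within each stream. Occupation is
#' collapsed to resident-physician vs all others for modelling even
#' though five categories exist in the data.
#'
#' @param retention Data frame from [build_retention_table()]:
#'   `user_id`, `stream`, `duration_days`, `event`, `platform`,
#'   `occupation`.
#' @param univariable If `TRUE`, fit one single-covariate Cox model per
#'   factor instead of the default joint two-covariate model per
#'   stream.
#' @param ties Tie-handling method passed to [cox_ph()].
#' @return An object of class `"retention_models"`: a list with `cox`
#'   (per stream; each a `cox_fit`, or a list of two univariable fits),
#'   `km` (per stream), `km_platform` (per stream and platform),
#'   `logrank` (`stream` comparison plus per-stream platform
#'   comparisons), and `univariable`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_users = 120, seed = 7))
#' rt <- build_retention_table(coh)
#' fit_retention_models(rt)
#' }
#' @export
fit_retention_models <- function(retention, univariable = FALSE,
                                 ties = "efron") {
  req <- c("user_id", "stream", "duration_days", "event", "platform",
           "occupation")
  stopifnot(is.data.frame(retention), all(req %in% names(retention)))
  if (nrow(retention) == 0L) {
    stop("no records in the retention table", call. = FALSE)
  }
  streams <- intersect(c("passive", "active"), unique(retention$stream))
  if (length(streams) < 2L) {
    stop("the retention table must contain both streams", call. = FALSE)
  }
  cox <- km <- km_platform <- vector("list", 0)
  logrank <- list(stream = log_rank(retention$duration_days,
                                    retention$event, retention$stream))
  for (s in streams) {
    d <- retention[retention$stream == s, , drop = FALSE]
    X <- cbind(ios = as.numeric(d$platform == "ios"),
               resident = as.numeric(d$occupation == "resident_physician"))
    cox[[s]] <- if (univariable) {
      list(ios = cox_ph(d$duration_days, d$event,
                        X[, "ios", drop = FALSE], ties = ties),
           resident = cox_ph(d$duration_days, d$event,
                             X[, "resident", drop = FALSE], ties = ties))
    } else {
      cox_ph(d$duration_days, d$event, X, ties = ties)
    }
    km[[s]] <- kaplan_meier(d$duration_days, d$event)
    for (pf in sort(unique(d$platform))) {
      dp <- d[d$platform == pf, , drop = FALSE]
      km_platform[[paste(s, pf, sep = ".")]] <-
        kaplan_meier(dp$duration_days, dp$event)
    }
    if (length(unique(d$platform)) == 2L) {
      logrank[[paste0(s, "_platform")]] <-
        log_rank(d$duration_days, d$event, d$platform)
    }
  }
  structure(list(cox = cox, km = km, km_platform = km_platform,
                 logrank = logrank, univariable = univariable),
            class = "retention_models")
}

#' @export
print.retention_models <- function(x, digits = 3, ...) {
  cat("Retention survival analysis (per-stream Cox",
      if (x$univariable) "univariable" else "joint", "fits)\n\n")
  for (s in names(x$km)) {
    k <- x$km[[s]]
    cat(sprintf("%s stream: n = %d, events = %d, S(7) = %.1f%%, S(28) = %.1f%%\n",
                s, k$n, k$n_events,
                100 * survival_at(k, 7), 100 * survival_at(k, 28)))
  }
  cat("\nHazard ratios (95% CI):\n")
  for (s in names(x$cox)) {
    fits <- if (x$univariable) x$cox[[s]] else list(joint = x$cox[[s]])
    for (nm in names(fits)) {
      f <- fits[[nm]]
      for (j in seq_along(f$coefficients)) {
        cat(sprintf("  %-8s %-9s HR = %.3f (%.3f-%.3f), p = %.3f\n",
                    s, names(f$coefficients)[j], f$hazard_ratio[j],
                    f$ci_lower[j], f$ci_upper[j], f$p_value[j]))
      }
    }
  }
  cat("\nLog-rank tests:\n")
  for (nm in names(x$logrank)) {
    lr <- x$logrank[[nm]]
    cat(sprintf("  %-18s chi-square = %.3f, p = %.3f\n",
                nm, lr$chi_square, lr$p_value))
  }
  invisible(x)
}
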