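#' Calibrate piecewise-exponential churn hazards from survival readouts
#'
#' Inverts the week and month survival probabilities of a retention
#' curve into constant daily hazards on days 0-7 and 7-28:
#' \eqn{\lambda_1 = -\log(S_7)/7} and
#' \eqn{\lambda_2 = -\log(S_{28}/S_7)/21}. The round trip is exact:
#' the implied curve passes through both readouts.
#'
#' @param s_week Survival probability at day 7, in (0, 1].
#' @param s_month Survival probability at day 28; must satisfy
#'   `0 < s_month <= s_week`.
#' @return Named numeric vector `c(lambda1, lambda2)` of daily hazards.
#' @examples
#' calibrate_hazards(0.467, 0.273)
#' @export
calibrate_hazards <- function(s_week, s_month) {
  stopifnot(is.numeric(s_week), is.numeric(s_month),
            length(s_week) == 1L, length(s_month) == 1L)
  if (!(s_month > 0 && s_week <= 1 && s_month <= s_week)) {
    stop("need 0 < s_month <= s_week <= 1", call. = FALSE)
  }
  c(lambda1 = -log(s_week) / 7, lambda2 = -log(s_month / s_week) / 21)
}

#' Sample piecewise-exponential event times
#'
#' Draws continuous event times from a piecewise-constant hazard with
#' change points at days 7 and 28 (rates `rates[1]` on \[0,7),
#' `rates[2]` on \[7,28), `rates[3]` on \[28,Inf)). A zero tail rate can
#' produce infinite times (no event).
#'
#' @param n Number of draws.
#' @param rates Numeric vector of three non-negative daily hazards.
#' @param breaks Change points, default `c(7, 28)`.
#' @return Numeric vector of event times in days (possibly `Inf`).
#' @export
sample_piecewise_exp <- function(n, rates, breaks = c(7, 28)) {
  stopifnot(length(rates) == 3L, all(rates >= 0), length(breaks) == 2L,
            breaks[1] > 0, breaks[2] > breaks[1])
  e <- stats::rexp(n)  # target cumulative hazard
  h1 <- rates[1] * breaks[1]
  h2 <- h1 + rates[2] * (breaks[2] - breaks[1])
  t <- numeric(n)
  seg1 <- e < h1
  t[seg1] <- e[seg1] / rates[1]
  seg2 <- !seg1 & e < h2
  t[seg2] <- breaks[1] + (e[seg2] - h1) / rates[2]
  seg3 <- !seg1 & !seg2
  t[seg3] <- if (rates[3] > 0) breaks[2] + (e[seg3] - h2) / rates[3] else Inf
  t
}

# Survival function of the same piecewise-exponential model.
piecewise_exp_survival <- function(t, rates, breaks = c(7, 28)) {
  h <- rates[1] * pmin(t, breaks[1]) +
    rates[2] * pmax(0, pmin(t, breaks[2]) - breaks[1]) +
    rates[3] * pmax(0, t - breaks[2])
  exp(-h)
}

#' Default per-stream, per-platform churn hazards
#'
#' Piecewise-exponential daily hazards (days 0-7, 7-28, 28+) for each
#' data stream and platform, calibrated with [calibrate_hazards()] from
#' the week/month retention levels of the study this package models:
#' passive Android 69.2%/49.5%, passive iOS 36.2%/16.7%, active Android
#' 8.3%/0.8%, active iOS 28.6%/4.5%. The post-day-28 hazard continues
#' the day 7-28 rate (no information beyond one month is available to
#' calibrate it).
#'
#' @return A nested list `hazards[[stream]][[platform]]`, each a
#'   3-vector of daily rates.
#' @export
default_churn_hazards <- function() {
  mk <- function(s7, s28) {
    l <- calibrate_hazards(s7, s28)
    c(l[["lambda1"]], l[["lambda2"]], l[["lambda2"]])
  }
  list(passive = list(android = mk(0.692, 0.495), ios = mk(0.362, 0.167)),
       active = list(android = mk(0.083, 0.008), ios = mk(0.286, 0.045)))
}

#' Stream-level uniform churn hazards
#'
#' Convenience for calibration studies: the same hazard triple for both
#' platforms of a stream, from stream-level week/month survival
#' readouts (tail rate continues the second rate unless given).
#'
#' @param s_week,s_month Stream-level survival at day 7 and day 28.
#' @param tail_rate Optional hazard after day 28; default: the day 7-28
#'   rate.
#' @return A list with `android` and `ios` entries (identical).
#' @export
uniform_hazards <- function(s_week, s_month, tail_rate = NULL) {
  l <- calibrate_hazards(s_week, s_month)
  r <- c(l[["lambda1"]], l[["lambda2"]],
         if (is.null(tail_rate)) l[["lambda2"]] else tail_rate)
  list(android = r, ios = r)
}

#' Commuter trace geometry
#'
#' Geometry of the simulated commuter: home and workplace coordinates,
#' GPS fix interval, position noise and fix dropout.
#'
#' @param home_lat,home_lon Home coordinates (decimal degrees). Default:
#'   a residential point about 6 km from the workplace.
#' @param work_lat,work_lon Workplace coordinates.
#' @param fix_interval_min Minutes between fixes. Default 10.
#' @param noise_sd_m Standard deviation of isotropic Gaussian position
#'   noise, metres. Default 20 (typical urban smartphone GPS error).
#' @param dropout Probability that any individual fix is missing.
#'   Default 0.05.
#' @return An object of class `"trace_geometry"`.
#' @export
trace_geometry <- function(home_lat = 25.09, home_lon = 121.52,
                           work_lat = 25.041, work_lon = 121.535,
                           fix_interval_min = 10, noise_sd_m = 20,
                           dropout = 0.05) {
  stopifnot(fix_interval_min > 0, noise_sd_m >= 0,
            dropout >= 0, dropout <= 1)
  structure(list(home_lat = home_lat, home_lon = home_lon,
                 work_lat = work_lat, work_lon = work_lon,
                 fix_interval_min = fix_interval_min,
                 noise_sd_m = noise_sd_m, dropout = dropout),
            class = "trace_geometry")
}

#' Synthetic cohort configuration
#'
#' Generative parameters for a synthetic app-user cohort: cohort size
#' and covariate mix, registration window and study cutoff,
#' piecewise-exponential churn hazards per data stream and platform,
#' an optional multiplicative occupation effect, and the trace
#' geometry. Defaults reproduce the enrolment structure of the study
#' this package models: 342 users, Android share 0.318 (solved from the
#' platform-stratified and pooled passive retention levels), occupation
#' counts 128 resident physicians / 60 visiting staff / 40 medical
#' students / 58 nurses / 56 others (128 residents and 286 medical
#' staff among 342), age 33.76 (SD 7.01, range 20-59), 224 men.
#'
#' @param n_users Number of demographically complete users. Default 342.
#' @param platform_mix Named proportions over `android`, `ios`.
#' @param occupation_mix Named proportions over the five occupation
#'   categories (assigned as exact counts, largest-remainder rounding,
#'   then shuffled).
#' @param age_mean,age_sd,age_range Age distribution (normal, truncated
#'   to the range).
#' @param prop_male Proportion of men.
#' @param registration_window Two dates: registrations are uniform over
#'   this range. Default 2018-08-01..2019-01-31, leaving every user at
#'   least 59 days of observation before the cutoff.
#' @param study_cutoff End of observation. Default 2019-03-31.
#' @param churn_hazards Nested list `[[stream]][[platform]]` of 3-vector
#'   daily hazards (days 0-7, 7-28, 28+); see
#'   [default_churn_hazards()], [uniform_hazards()].
#' @param occupation_hr Named vector: multiplicative hazard ratio of the
#'   resident-physician group vs all others, per stream. Default 1
#'   (platform curves are the calibration anchors).
#' @param active_cadence `"daily"` (default): active engagement events
#'   occur daily while the user is retained on the active stream, so
#'   the 28-day silence rule measures the configured churn process;
#'   `"monthly"`: surveys land only on first-of-month dates, emulating
#'   the app's true cadence (under which any month-to-month gap already
#'   exceeds 28 days).
#' @param trace_days Number of initial workdays for which GPS traces
#'   are generated per user (0 = no traces). Default 0.
#' @param geometry A [trace_geometry()].
#' @param missing_demographics Number of additional users enrolled
#'   without demographic data (they upload, but are excluded by
#'   [apply_exclusions()]). Default 0.
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical.
#' @return An object of class `"cohort_config"`.
#' @examples
#' cohort_config(n_users = 50, seed = 1)
#' @export
cohort_config <- function(n_users = 342,
                          platform_mix = c(android = 0.318, ios = 0.682),
                          occupation_mix = c(resident_physician = 128,
                                             visiting_staff = 60,
                                             medical_student = 40,
                                             nurse = 58,
                                             other = 56) / 342,
                          age_mean = 33.76, age_sd = 7.01,
                          age_range = c(20, 59),
                          prop_male = 224 / 342,
                          registration_window = as.Date(c("2018-08-01",
                                                          "2019-01-31")),
                          study_cutoff = as.Date("2019-03-31"),
                          churn_hazards = default_churn_hazards(),
                          occupation_hr = c(passive = 1, active = 1),
                          active_cadence = c("daily", "monthly"),
                          trace_days = 0,
                          geometry = trace_geometry(),
                          missing_demographics = 0,
                          seed = 20180801) {
  active_cadence <- match.arg(active_cadence)
  stopifnot(n_users >= 1, missing_demographics >= 0, trace_days >= 0)
  if (abs(sum(platform_mix) - 1) > 1e-8 || any(platform_mix < 0)) {
    stop("platform_mix must be non-negative and sum to 1", call. = FALSE)
  }
  if (abs(sum(occupation_mix) - 1) > 1e-8 || any(occupation_mix < 0)) {
    stop("occupation_mix must be non-negative and sum to 1", call. = FALSE)
  }
  for (s in c("passive", "active")) {
    for (pf in c("android", "ios")) {
      r <- churn_hazards[[s]][[pf]]
      if (is.null(r) || length(r) != 3L || any(r < 0)) {
        stop("churn_hazards$", s, "$", pf,
             " must be 3 non-negative rates", call. = FALSE)
      }
    }
  }
  registration_window <- as.Date(registration_window)
  study_cutoff <- as.Date(study_cutoff)
  if (registration_window[2] > study_cutoff) {
    stop("registrations cannot extend past the study cutoff", call. = FALSE)
  }
  structure(list(n_users = as.integer(n_users),
                 platform_mix = platform_mix,
                 occupation_mix = occupation_mix,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 prop_male = prop_male,
                 registration_window = registration_window,
                 study_cutoff = study_cutoff,
                 churn_hazards = churn_hazards,
                 occupation_hr = occupation_hr,
                 active_cadence = active_cadence,
                 trace_days = as.integer(trace_days),
                 geometry = geometry,
                 missing_demographics = as.integer(missing_demographics),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort config:", x$n_users, "users",
      if (x$missing_demographics)
        paste0("(+", x$missing_demographics, " without demographics)"),
      "\n  registrations", format(x$registration_window[1]), "to",
      format(x$registration_window[2]), "; cutoff",
      format(x$study_cutoff), "\n  active cadence:", x$active_cadence,
      "; trace days:", x$trace_days, "; seed:", x$seed, "\n")
  invisible(x)
}

# Exact counts from proportions by largest-remainder rounding.
exact_counts <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic app-user cohort
#'
#' Draws users (covariates and registration dates), per-stream true
#' churn times from the configured piecewise-exponential hazards, and
#' the upload logs implied by them: passive uploads every day while
#' retained, active events per the configured cadence. Ground-truth
#' churn days are recorded so downstream retention logic can be checked
#' against the truth. All randomness flows from `config$seed`;
#' identical configs produce identical cohorts.
#'
#' @param config A [cohort_config()].
#' @return An object of class `"synthetic_cohort"`: `users` (one row
#'   per user: `user_id`, `registration`, `platform`, `occupation`,
#'   `age`, `gender`), `uploads` (`user_id`, `stream`, `time` as
#'   `Date`, `day`), `ground_truth` (`user_id`, `stream`,
#'   `true_churn_day`, `true_time`; `NA` churn day = never churns),
#'   `workplaces` and `gps` (when `trace_days > 0`), and `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_users = 20, seed = 42))
#' head(coh$users)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_users
  n_all <- n + config$missing_demographics
  ids <- sprintf("u%04d", seq_len(n_all))

  platform <- rep(names(config$platform_mix),
                  exact_counts(config$platform_mix, n))
  occupation <- rep(names(config$occupation_mix),
                    exact_counts(config$occupation_mix, n))
  n_male <- round(config$prop_male * n)
  gender <- rep(c("male", "female"), c(n_male, n - n_male))
  platform <- sample(platform)
  occupation <- sample(occupation)
  gender <- sample(gender)
  age <- round(truncated_normal(n, config$age_mean, config$age_sd,
                                config$age_range), 1)
  if (config$missing_demographics > 0) {
    # users who uploaded but never provided demographics; platform is
    # still known to the server, the questionnaire fields are not
    platform <- c(platform,
                  sample(names(config$platform_mix),
                         config$missing_demographics, replace = TRUE,
                         prob = config$platform_mix))
    occupation <- c(occupation, rep(NA_character_,
                                    config$missing_demographics))
    age <- c(age, rep(NA_real_, config$missing_demographics))
    gender <- c(gender, rep(NA_character_, config$missing_demographics))
  }
  win <- config$registration_window
  registration <- win[1] +
    sample.int(as.integer(win[2] - win[1]) + 1L, n_all, replace = TRUE) - 1L
  users <- data.frame(user_id = ids, registration = registration,
                      platform = platform, occupation = occupation,
                      age = age, gender = gender)
  horizon <- as.integer(config$study_cutoff - registration)

  uploads <- list()
  gt <- list()
  for (s in c("passive", "active")) {
    rates <- t(vapply(platform, function(pf) config$churn_hazards[[s]][[pf]],
                      numeric(3)))
    hr <- ifelse(!is.na(occupation) & occupation == "resident_physician",
                 config$occupation_hr[[s]], 1)
    tt <- numeric(n_all)
    # one uniform-rate draw per user via the shared piecewise sampler
    e <- stats::rexp(n_all)
    h1 <- rates[, 1] * 7
    h2 <- h1 + rates[, 2] * 21
    e <- e / hr  # multiplicative hazard: scales the cumulative hazard
    tt <- ifelse(e < h1, e / rates[, 1],
                 ifelse(e < h2, 7 + (e - h1) / rates[, 2],
                        ifelse(rates[, 3] > 0, 28 + (e - h2) / rates[, 3],
                               Inf)))
    churn_day <- floor(tt)
    last_day <- pmin(churn_day, horizon)
    if (s == "passive" || config$active_cadence == "daily") {
      kk <- pmax(last_day, 0)
      up_user <- rep(ids, kk + 1)
      up_day <- unlist(lapply(kk, function(k) 0:k), use.names = FALSE)
      up_reg <- rep(registration, kk + 1)
    } else {
      per <- lapply(seq_len(n_all), function(i) {
        month_first_days(registration[i], last_day[i])
      })
      lens <- lengths(per)
      up_user <- rep(ids, lens)
      up_day <- unlist(per, use.names = FALSE)
      up_reg <- rep(registration, lens)
    }
    uploads[[s]] <- data.frame(user_id = up_user, stream = s,
                               time = up_reg + up_day, day = up_day)
    gt[[s]] <- data.frame(user_id = ids, stream = s,
                          true_churn_day = ifelse(is.finite(churn_day),
                                                  churn_day, NA_real_),
                          true_time = tt)
  }
  uploads <- do.call(rbind, uploads)
  uploads <- uploads[order(uploads$user_id, uploads$stream, uploads$day), ]
  rownames(uploads) <- NULL
  ground_truth <- do.call(rbind, gt)
  ground_truth <- ground_truth[order(ground_truth$user_id,
                                     ground_truth$stream), ]
  rownames(ground_truth) <- NULL

  out <- list(users = users, uploads = uploads, ground_truth = ground_truth,
              config = config)
  if (config$trace_days > 0) {
    g <- config$geometry
    out$workplaces <- data.frame(user_id = ids, workplace_id = "w1",
                                 lat = g$work_lat, lon = g$work_lon)
    traces <- vector("list", n_all)
    for (i in seq_len(n_all)) {
      dates <- registration[i] + seq_len(config$trace_days) - 1L
      traces[[i]] <- generate_trace(ids[i], dates, geometry = g)
    }
    out$gps <- do.call(rbind, traces)
    rownames(out$gps) <- NULL
  }
  structure(out, class = "synthetic_cohort")
}

# first-of-month upload days within [0, last_day] for a registration date
month_first_days <- function(registration, last_day) {
  if (last_day < 0) return(integer(0))
  end <- registration + last_day
  first <- as.Date(format(registration, "%Y-%m-01"))
  firsts <- seq(first, by = "month", length.out = 1L +
                  ceiling(as.numeric(end - first) / 28) + 1L)
  d <- as.integer(firsts - registration)
  d[d >= 0 & d <= last_day]
}

truncated_normal <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < range[1] | x > range[2])
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < range[1] | x[bad] > range[2]]
  }
  x
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$users), "users,",
      nrow(x$uploads), "uploads",
      if (!is.null(x$gps)) paste0(", ", nrow(x$gps), " GPS fixes"), "\n")
  cat("  events by stream within window:\n")
  gt <- x$ground_truth
  horizon <- as.integer(x$config$study_cutoff -
                          x$users$registration[match(gt$user_id,
                                                     x$users$user_id)])
  for (s in c("passive", "active")) {
    sel <- gt$stream == s
    obs <- sum(!is.na(gt$true_churn_day[sel]) &
                 gt$true_churn_day[sel] <= horizon[sel])
    cat("   ", s, ":", obs, "true churn events\n")
  }
  invisible(x)
}

#' Generate one user's commuter GPS trace
#'
#' Emits fixes at the configured interval over each requested date:
#' positioned at the workplace during the scheduled presence window and
#' at home otherwise, with isotropic Gaussian position noise and
#' independent fix dropout.
#'
#' @param user_id User identifier.
#' @param dates Vector of `Date`s to simulate.
#' @param work_start,work_end Daily presence window at the workplace,
#'   `"HH:MM"` strings. Defaults 08:50-18:20.
#' @param geometry A [trace_geometry()].
#' @param tz Timezone of the schedule. Default `"Asia/Taipei"`.
#' @return Data frame `user_id`, `time` (POSIXct), `lat`, `lon`.
#' @examples
#' tr <- generate_trace("u1", as.Date("2018-09-03"),
#'                      geometry = trace_geometry(noise_sd_m = 0,
#'                                                dropout = 0))
#' nrow(tr)
#' @export
generate_trace <- function(user_id, dates, work_start = "08:50",
                           work_end = "18:20",
                           geometry = trace_geometry(),
                           tz = "Asia/Taipei") {
  stopifnot(inherits(geometry, "trace_geometry"))
  dates <- as.Date(dates)
  out <- vector("list", length(dates))
  for (i in seq_along(dates)) {
    day0 <- as.POSIXct(paste(dates[i], "00:00:00"), tz = tz)
    mins <- seq(0, 24 * 60 - geometry$fix_interval_min,
                by = geometry$fix_interval_min)
    tt <- day0 + mins * 60
    ws <- as.POSIXct(paste(dates[i], work_start), format = "%Y-%m-%d %H:%M",
                     tz = tz)
    we <- as.POSIXct(paste(dates[i], work_end), format = "%Y-%m-%d %H:%M",
                     tz = tz)
    at_work <- tt >= ws & tt <= we
    lat <- ifelse(at_work, geometry$work_lat, geometry$home_lat)
    lon <- ifelse(at_work, geometry$work_lon, geometry$home_lon)
    if (geometry$noise_sd_m > 0) {
      m_per_deg_lat <- 1000 * EARTH_RADIUS_KM * pi / 180
      lat <- lat + stats::rnorm(length(lat), 0,
                                geometry$noise_sd_m / m_per_deg_lat)
      lon <- lon + stats::rnorm(length(lon), 0,
                                geometry$noise_sd_m /
                                  (m_per_deg_lat * cos(lat * pi / 180)))
    }
    keep <- stats::runif(length(tt)) >= geometry$dropout
    out[[i]] <- data.frame(user_id = user_id, time = tt,
                           lat = lat, lon = lon)[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
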