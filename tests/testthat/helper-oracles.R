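# Independent oracles and fixture builders used across the suite.

# Spherical law of cosines: an independent great-circle formula.
sloc_km <- function(lat1, lon1, lat2, lon2) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  x <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  6371.0 * acos(pmin(pmax(x, -1), 1))
}

# Brute-force day-by-day churn scan over the daily upload indicator:
# walks the calendar one day at a time, counting elapsed days since the
# last contact (registration = day-0 contact), and declares churn the
# moment `gap_days` silent days have accumulated -- before crediting an
# upload landing on that same day, mirroring the "first date of a
# silent period" reading.
oracle_churn <- function(days, horizon, gap_days = 28,
                         anchor = c("gap_start", "last_upload")) {
  anchor <- match.arg(anchor)
  days <- days[days >= 0 & days <= horizon]
  has <- rep(FALSE, horizon + 1L)
  has[days + 1L] <- TRUE
  last <- 0L
  for (t in seq_len(horizon)) {
    if (t - last >= gap_days) {
      dur <- if (anchor == "last_upload") last else last + 1L
      return(list(duration_days = dur, event = 1L))
    }
    if (has[t + 1L]) last <- t
  }
  list(duration_days = as.integer(horizon), event = 0L)
}

# Random upload log on the day grid.
random_upload_days <- function(horizon, p_upload = NULL) {
  if (is.null(p_upload)) p_upload = stats::runif(1, 0.01, 0.5)
  sort(unique(c(0L, which(stats::runif(horizon) < p_upload))))
}

# A one-user trace: fixes at `minutes` offsets from a base time, at the
# workplace when `at_work` is TRUE and ~8 km away otherwise.
make_trace <- function(minutes, at_work,
                       base = as.POSIXct("2018-09-03 00:00:00",
                                         tz = "Asia/Taipei"),
                       user_id = "u1") {
  data.frame(user_id = user_id,
             time = base + minutes * 60,
             lat = ifelse(at_work, 25.041, 25.11),
             lon = ifelse(at_work, 121.535, 121.52))
}

toy_workplace <- function() {
  data.frame(workplace_id = "w1", lat = 25.041, lon = 121.535)
}

# Random small right-censored dataset for oracle-equivalence checks.
random_surv_data <- function(n = 30, p = 1, ties = TRUE, event_p = 0.7) {
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  beta <- stats::runif(p, -0.8, 0.8)
  t <- stats::rexp(n, 0.1 * exp(drop(x %*% beta)))
  if (ties) t <- ceiling(t * 2) / 2  # coarse grid forces tied times
  status <- stats::rbinom(n, 1, event_p)
  if (sum(status) < 2) status[sample(n, 2)] <- 1L
  list(time = t, status = status, x = x)
}

# Deterministic enrolment fixture mirroring the study's head counts:
# `n_complete` users with demographics (occupation counts fixed) plus
# `n_missing` users who uploaded but never filled in the questionnaire.
enrollment_fixture <- function(n_complete = 342, n_missing = 79,
                               occupation_counts = NULL) {
  if (is.null(occupation_counts)) {
    template <- c(resident_physician = 128, visiting_staff = 60,
                  medical_student = 40, nurse = 58, other = 56)
    raw <- template / 342 * n_complete
    occupation_counts <- floor(raw)
    short <- n_complete - sum(occupation_counts)
    if (short > 0) {
      bump <- order(raw - floor(raw), decreasing = TRUE)[seq_len(short)]
      occupation_counts[bump] <- occupation_counts[bump] + 1
    }
  }
  stopifnot(sum(occupation_counts) == n_complete)
  n <- n_complete + n_missing
  ids <- sprintf("u%04d", seq_len(n))
  reg <- as.Date("2018-08-01") + (seq_len(n) %% 120)
  occ <- c(rep(names(occupation_counts), occupation_counts),
           rep(NA_character_, n_missing))
  users <- data.frame(user_id = ids, registration = reg,
                      platform = rep(c("android", "ios"), length.out = n),
                      occupation = occ,
                      age = ifelse(is.na(occ), NA_real_, 34),
                      gender = ifelse(is.na(occ), NA_character_, "male"))
  uploads <- data.frame(user_id = ids, stream = "passive", time = reg)
  list(users = users, uploads = uploads)
}
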