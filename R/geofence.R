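#' Geofence detection parameters
#'
#' Parameters of the workplace geofence algorithm: detection radius,
#' nominal GPS sampling interval, and the confirmation (hysteresis)
#' window that a run of in-range or out-of-range fixes must span before
#' it opens or closes a work session.
#'
#' @param radius_km Detection radius around each workplace, km. Default 1.
#' @param sample_interval_min Nominal GPS sampling interval, minutes.
#'   Default 10.
#' @param confirm_min Confirmation window, minutes: a run of same-state
#'   fixes must span at least this long (first to last fix) to change the
#'   session state. Default 30. Must be at least `sample_interval_min`.
#' @return An object of class `"geofence_params"`.
#' @examples
#' geofence_params()
#' geofence_params(radius_km = 0.5, confirm_min = 20)
#' @export
geofence_params <- function(radius_km = 1.0, sample_interval_min = 10,
                            confirm_min = 30) {
  stopifnot(is.numeric(radius_km), length(radius_km) == 1L,
            is.numeric(sample_interval_min), length(sample_interval_min) == 1L,
            is.numeric(confirm_min), length(confirm_min) == 1L)
  if (radius_km <= 0 || sample_interval_min <= 0 || confirm_min <= 0) {
    stop("geofence parameters must be strictly positive", call. = FALSE)
  }
  if (confirm_min < sample_interval_min) {
    stop("confirm_min must be >= sample_interval_min", call. = FALSE)
  }
  structure(list(radius_km = radius_km,
                 sample_interval_min = sample_interval_min,
                 confirm_min = confirm_min),
            class = "geofence_params")
}

#' @export
print.geofence_params <- function(x, ...) {
  cat("Geofence parameters: radius", x$radius_km, "km;",
      "sampling every", x$sample_interval_min, "min;",
      "confirmation window", x$confirm_min, "min\n")
  invisible(x)
}

validate_workplaces <- function(workplaces) {
  if (!is.data.frame(workplaces) || nrow(workplaces) == 0L) {
    stop("at least one workplace must be registered", call. = FALSE)
  }
  req <- c("workplace_id", "lat", "lon")
  if (!all(req %in% names(workplaces))) {
    stop("workplaces need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(workplaces) > 5L) {
    stop("at most 5 workplaces can be tracked per user", call. = FALSE)
  }
  workplaces
}

#' Is a GPS fix within range of any registered workplace?
#'
#' A fix is in range when its distance to the nearest workplace is at
#' most the detection radius (the boundary itself counts as in range).
#' The nearest workplace is reported for bookkeeping; ties are broken by
#' registration order (row order of `workplaces`).
#'
#' @param lat,lon Numeric vectors of fix coordinates (decimal degrees).
#' @param workplaces Data frame with columns `workplace_id`, `lat`, `lon`;
#'   1 to 5 rows.
#' @param params A [geofence_params()] object.
#' @return A data frame with one row per fix: `in_range` (logical),
#'   `workplace_id` (nearest workplace), `dist_km` (distance to it).
#' @examples
#' wp <- data.frame(workplace_id = "w1", lat = 25.0, lon = 121.5)
#' fix_in_range(c(25.0, 25.2), c(121.5, 121.5), wp)
#' @export
fix_in_range <- function(lat, lon, workplaces, params = geofence_params()) {
  workplaces <- validate_workplaces(workplaces)
  stopifnot(inherits(params, "geofence_params"), length(lat) == length(lon))
  n <- length(lat)
  k <- nrow(workplaces)
  d <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    d[, j] <- haversine_km(lat, lon, workplaces$lat[j], workplaces$lon[j])
  }
  nearest <- max.col(-d, ties.method = "first")
  dist_km <- d[cbind(seq_len(n), nearest)]
  # closed ball; the 1e-9 km (1 micrometre) slack keeps points placed
  # exactly on the boundary in range despite floating-point round-off
  data.frame(in_range = dist_km <= params$radius_km + 1e-9,
             workplace_id = workplaces$workplace_id[nearest],
             dist_km = dist_km)
}

#' Detect work sessions from a single user's GPS trace
#'
#' Runs the geofence state machine over an ordered GPS fix stream.
#' A session opens at the first fix of a run of consecutive in-range
#' fixes once that run spans at least `confirm_min` minutes (the start is
#' assigned retroactively to the run's first fix). An open session closes
#' at the last in-range fix when a run of out-of-range fixes spans at
#' least `confirm_min` minutes, or when the trace has a gap of at least
#' `confirm_min` minutes with no fixes at all (missing data is treated
#' conservatively as absence). Shorter out-of-range excursions or gaps do
#' not split a session. A trace that ends while a session is open closes
#' the session at the last in-range fix and flags it `open_at_end`.
#'
#' @param fixes Data frame with columns `user_id`, `time` (POSIXct,
#'   strictly increasing), `lat`, `lon`; a single user's trace.
#' @param workplaces Data frame of that user's workplaces
#'   (`workplace_id`, `lat`, `lon`; 1 to 5 rows).
#' @param params A [geofence_params()] object.
#' @return Data frame of sessions: `user_id`, `start`, `end` (POSIXct),
#'   `duration_min`, `open_at_end` (logical).
#' @seealso [daily_work_hours()] to aggregate sessions into daily totals.
#' @export
detect_sessions <- function(fixes, workplaces, params = geofence_params()) {
  workplaces <- validate_workplaces(workplaces)
  stopifnot(inherits(params, "geofence_params"))
  if (!is.data.frame(fixes) ||
      !all(c("user_id", "time", "lat", "lon") %in% names(fixes))) {
    stop("fixes need columns: user_id, time, lat, lon", call. = FALSE)
  }
  if (nrow(fixes) == 0L) {
    return(empty_sessions())
  }
  if (length(unique(fixes$user_id)) > 1L) {
    stop("detect_sessions expects a single user's trace", call. = FALSE)
  }
  if (!inherits(fixes$time, "POSIXct")) {
    stop("fixes$time must be POSIXct", call. = FALSE)
  }
  tmin <- as.numeric(fixes$time) / 60  # minutes
  if (is.unsorted(tmin, strictly = TRUE)) {
    stop("trace timestamps must be strictly increasing", call. = FALSE)
  }
  inr <- fix_in_range(fixes$lat, fixes$lon, workplaces, params)$in_range
  confirm <- params$confirm_min

  starts <- ends <- numeric(0)    # indices into fixes
  open <- FALSE
  sess_start <- NA_integer_       # index of session start fix
  last_in <- NA_integer_          # index of last in-range fix
  cand_start <- NA_integer_       # first fix of candidate opening run
  out_start <- NA_integer_        # first fix of current out-of-range run

  close_session <- function() {
    starts <<- c(starts, sess_start)
    ends <<- c(ends, last_in)
  }

  n <- nrow(fixes)
  for (i in seq_len(n)) {
    if (i > 1L && (tmin[i] - tmin[i - 1L]) >= confirm) {
      # a silent gap as long as the confirmation window: treat as absence
      if (open) {
        close_session()
        open <- FALSE
      }
      cand_start <- NA_integer_
      out_start <- NA_integer_
    }
    if (inr[i]) {
      if (open) {
        last_in <- i
        out_start <- NA_integer_
      } else {
        if (is.na(cand_start)) cand_start <- i
        if (tmin[i] - tmin[cand_start] >= confirm) {
          open <- TRUE
          sess_start <- cand_start
          last_in <- i
          out_start <- NA_integer_
        }
      }
    } else {
      if (open) {
        if (is.na(out_start)) out_start <- i
        if (tmin[i] - tmin[out_start] >= confirm) {
          close_session()
          open <- FALSE
          out_start <- NA_integer_
        }
      }
      cand_start <- NA_integer_
    }
  }
  open_flags <- rep(FALSE, length(starts))
  if (open) {
    close_session()
    open_flags <- c(open_flags, TRUE)
  }
  if (length(starts) == 0L) {
    return(empty_sessions())
  }
  data.frame(user_id = fixes$user_id[1L],
             start = fixes$time[starts],
             end = fixes$time[ends],
             duration_min = (tmin[ends] - tmin[starts]),
             open_at_end = open_flags)
}

empty_sessions <- function() {
  data.frame(user_id = character(0),
             start = as.POSIXct(character(0)),
             end = as.POSIXct(character(0)),
             duration_min = numeric(0),
             open_at_end = logical(0))
}

#' Daily work hours from detected sessions
#'
#' Intersects work sessions with calendar days in the user's local
#' timezone and sums the overlapping durations. Sessions crossing local
#' midnight are split at the day boundary. Scheduled hours (regular plus
#' on-call) are subtracted to give signed overtime.
#'
#' @param sessions Data frame as returned by [detect_sessions()]
#'   (columns `user_id`, `start`, `end`).
#' @param scheduled_hours Either a single number applied to every
#'   user-day, or a data frame `user_id`, `scheduled_hours` (per-user
#'   constants). Default 8.
#' @param dates Optional vector of `Date`s to report; days without any
#'   session are filled with 0 total hours. Default: only days touched by
#'   a session.
#' @param tz Timezone used to define calendar days. Default
#'   `"Asia/Taipei"` (UTC+8), the app's market.
#' @return Data frame `user_id`, `date`, `total_hours`,
#'   `scheduled_hours`, `overtime_hours` ordered by user and date.
#' @export
daily_work_hours <- function(sessions, scheduled_hours = 8, dates = NULL,
                             tz = "Asia/Taipei") {
  stopifnot(is.data.frame(sessions))
  pieces <- list()
  for (i in seq_len(nrow(sessions))) {
    s <- as.POSIXct(sessions$start[i])
    e <- as.POSIXct(sessions$end[i])
    if (as.numeric(e) < as.numeric(s)) {
      stop("session end precedes start", call. = FALSE)
    }
    day <- as.Date(s, tz = tz)
    last_day <- as.Date(e, tz = tz)
    days <- seq(day, last_day, by = "day")
    for (d in seq_along(days)) {
      d0 <- as.POSIXct(paste(days[d], "00:00:00"), tz = tz)
      d1 <- d0 + 86400
      ov <- min(as.numeric(e), as.numeric(d1)) -
        max(as.numeric(s), as.numeric(d0))
      if (ov > 0) {
        pieces[[length(pieces) + 1L]] <-
          data.frame(user_id = sessions$user_id[i], date = days[d],
                     total_hours = ov / 3600)
      }
    }
  }
  if (length(pieces)) {
    out <- do.call(rbind, pieces)
    out <- stats::aggregate(total_hours ~ user_id + date, data = out, FUN = sum)
  } else {
    out <- data.frame(user_id = character(0), date = as.Date(character(0)),
                      total_hours = numeric(0))
  }
  if (!is.null(dates)) {
    users <- unique(c(out$user_id, as.character(sessions$user_id)))
    if (length(users) == 0L) users <- character(0)
    grid <- expand.grid(user_id = users, date = as.Date(dates),
                        stringsAsFactors = FALSE)
    out <- merge(grid, out, by = c("user_id", "date"), all.x = TRUE)
    out$total_hours[is.na(out$total_hours)] <- 0
  }
  sched <- scheduled_lookup(scheduled_hours, out$user_id)
  out$scheduled_hours <- sched
  out$overtime_hours <- overtime_hours(out$total_hours, out$scheduled_hours)
  out <- out[order(out$user_id, out$date), ]
  rownames(out) <- NULL
  out
}

scheduled_lookup <- function(scheduled_hours, user_ids) {
  if (is.data.frame(scheduled_hours)) {
    stopifnot(all(c("user_id", "scheduled_hours") %in% names(scheduled_hours)))
    idx <- match(user_ids, scheduled_hours$user_id)
    if (anyNA(idx) && length(user_ids)) {
      stop("scheduled_hours missing for some users", call. = FALSE)
    }
    scheduled_hours$scheduled_hours[idx]
  } else {
    stopifnot(is.numeric(scheduled_hours), length(scheduled_hours) == 1L)
    rep(as.numeric(scheduled_hours), length(user_ids))
  }
}

#' Signed overtime hours
#'
#' Overtime is GPS-derived total work hours minus user-scheduled work
#' hours (regular plus on-call). The difference is reported signed: a
#' user who worked less than scheduled has negative overtime.
#'
#' @param total_hours,scheduled_hours Non-negative numeric vectors
#'   (recycled to a common length).
#' @return Numeric vector `total_hours - scheduled_hours`.
#' @examples
#' overtime_hours(10, 8)   #  2
#' overtime_hours(6, 8)    # -2
#' @export
overtime_hours <- function(total_hours, scheduled_hours) {
  if (!is.numeric(total_hours) || !is.numeric(scheduled_hours) ||
      anyNA(total_hours) || anyNA(scheduled_hours)) {
    stop("work hours must be numeric and non-missing", call. = FALSE)
  }
  if (any(total_hours < 0) || any(scheduled_hours < 0)) {
    stop("work hours must be non-negative", call. = FALSE)
  }
  total_hours - scheduled_hours
}
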