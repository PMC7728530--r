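#' User-retention (churn) parameters
#'
#' @param gap_days Length of upload silence, in days, that defines churn.
#'   Default 28.
#' @param install_window_days Window after registration, in days, within
#'   which at least one upload must occur for the installation to count
#'   as successful. Default 28.
#' @param churn_anchor Which day is reported as the churn date when a
#'   qualifying silence is found: `"gap_start"` (default) dates churn to
#'   the first silent day, i.e. the first date of the `gap_days`-day
#'   period without any upload; `"last_upload"` dates it to the last
#'   upload preceding the silence (one day earlier).
#' @return An object of class `"retention_params"`.
#' @examples
#' retention_params()
#' retention_params(churn_anchor = "last_upload")
#' @export
retention_params <- function(gap_days = 28, install_window_days = 28,
                             churn_anchor = c("gap_start", "last_upload")) {
  churn_anchor <- match.arg(churn_anchor)
  stopifnot(is.numeric(gap_days), length(gap_days) == 1L,
            is.numeric(install_window_days), length(install_window_days) == 1L)
  if (gap_days <= 0 || install_window_days <= 0) {
    stop("gap_days and install_window_days must be positive", call. = FALSE)
  }
  structure(list(gap_days = as.integer(gap_days),
                 install_window_days = as.integer(install_window_days),
                 churn_anchor = churn_anchor),
            class = "retention_params")
}

#' @export
print.retention_params <- function(x, ...) {
  cat("Retention parameters: churn after", x$gap_days,
      "silent days; install window", x$install_window_days,
      "days; churn anchored at", x$churn_anchor, "\n")
  invisible(x)
}

#' Observation window of the study
#'
#' @param start First date of the observation period.
#' @param cutoff Last date of the observation period (administrative
#'   censoring date). Must be after `start`.
#' @return An object of class `"study_window"`.
#' @examples
#' study_window("2018-08-01", "2019-03-31")
#' @export
study_window <- function(start, cutoff) {
  start <- as.Date(start)
  cutoff <- as.Date(cutoff)
  if (anyNA(c(start, cutoff)) || start >= cutoff) {
    stop("study window requires start < cutoff", call. = FALSE)
  }
  structure(list(start = start, cutoff = cutoff), class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat("Study window:", format(x$start), "to", format(x$cutoff), "\n")
  invisible(x)
}

# Whole upload days since registration (floored, sorted, unique).
upload_days <- function(upload_times, registration) {
  if (length(upload_times) == 0L) return(integer(0))
  d <- floor(as.numeric(difftime(upload_times, registration, units = "days")))
  if (any(d < 0)) {
    stop("uploads precede registration", call. = FALSE)
  }
  sort(unique(as.integer(d)))
}

#' Did a user successfully install the app?
#'
#' Successful installation means at least one upload (on any data
#' stream) within the first `install_window_days` days of registration.
#'
#' @param upload_times Vector of upload times (`Date` or `POSIXct`);
#'   may be empty.
#' @param registration Registration date/time of the user.
#' @param params A [retention_params()] object.
#' @return `TRUE` or `FALSE`.
#' @examples
#' successful_installation(as.Date("2018-08-01"), as.Date("2018-08-01"))
#' successful_installation(as.Date(character(0)), as.Date("2018-08-01"))
#' @export
successful_installation <- function(upload_times, registration,
                                    params = retention_params()) {
  stopifnot(inherits(params, "retention_params"))
  d <- upload_days(upload_times, registration)
  any(d < params$install_window_days)
}

# Core day-grid churn scan. `days` are whole upload days since
# registration (sorted, unique, >= 0); `horizon` is the cutoff day.
# Registration itself (day 0) counts as contact, so the silence clock
# starts there. Re-entry after a qualifying silence is ignored: the
# earliest qualifying gap wins.
churn_scan <- function(days, horizon, gap_days, churn_anchor) {
  last <- 0L
  churned <- FALSE
  for (d in days) {
    if (d > horizon) break
    if (d - last >= gap_days) {
      churned <- TRUE
      break
    }
    last <- d
  }
  if (!churned && (horizon - last) >= gap_days) churned <- TRUE
  if (churned) {
    dur <- if (churn_anchor == "last_upload") last else last + 1L
    list(duration_days = as.integer(dur), event = 1L)
  } else {
    list(duration_days = as.integer(horizon), event = 0L)
  }
}

#' Churn time of one user on one data stream
#'
#' Scans the user's upload history for the first `gap_days`-day period
#' with no upload (the retention definition), treating registration
#' as day-0 contact and the cutoff as the end of observation. If such a
#' silence is fully observed before the cutoff the churn event is
#' recorded (`event = 1`) and the duration is the churn date per the
#' `churn_anchor` convention; otherwise the user is right-censored at
#' the cutoff (`event = 0`). Uploads after a qualifying silence are
#' ignored (no re-entry); uploads after the cutoff are not observed.
#'
#' @param upload_times Vector of the user's upload times on one stream
#'   (`Date` or `POSIXct`); may be empty.
#' @param registration The user's registration date.
#' @param cutoff End of observation (`Date`), or a [study_window()].
#' @param params A [retention_params()] object.
#' @return A list with `duration_days` (integer, whole days since
#'   registration) and `event` (1 = churn observed, 0 = censored).
#' @examples
#' reg <- as.Date("2018-09-01")
#' churn_time(reg + 0:9, reg, reg + 200)   # churns after day 9
#' @export
churn_time <- function(upload_times, registration, cutoff,
                       params = retention_params()) {
  stopifnot(inherits(params, "retention_params"))
  if (inherits(cutoff, "study_window")) cutoff <- cutoff$cutoff
  horizon <- floor(as.numeric(difftime(as.Date(cutoff), as.Date(registration),
                                       units = "days")))
  if (is.na(horizon) || horizon < 0) {
    stop("registration must be on or before the cutoff", call. = FALSE)
  }
  d <- upload_days(upload_times, registration)
  churn_scan(d, as.integer(horizon), params$gap_days, params$churn_anchor)
}

#' Apply the study's inclusion rules to a cohort
#'
#' Drops, in order, users with missing demographic data (platform,
#' occupation, age or gender) and then users without any upload during
#' the installation window. Matches the enrolment filtering of the
#' study design this package models.
#'
#' @param users Data frame with columns `user_id`, `registration`
#'   (`Date`), `platform`, `occupation`, `age`, `gender`.
#' @param uploads Data frame of all uploads, columns `user_id`,
#'   `stream`, `time` (`Date` or `POSIXct`).
#' @param params A [retention_params()] object.
#' @return A list: `included` (subset of `users`), `excluded` (data
#'   frame `user_id`, `reason`), `counts` (named vector: `total`,
#'   `missing_demographics`, `failed_installation`, `included`).
#' @export
apply_exclusions <- function(users, uploads, params = retention_params()) {
  stopifnot(is.data.frame(users),
            all(c("user_id", "registration", "platform", "occupation",
                  "age", "gender") %in% names(users)))
  miss <- is.na(users$platform) | is.na(users$occupation) |
    is.na(users$age) | is.na(users$gender)
  excluded <- data.frame(user_id = users$user_id[miss],
                         reason = rep("missing_demographics", sum(miss)))
  remaining <- users[!miss, , drop = FALSE]
  ok_install <- vapply(seq_len(nrow(remaining)), function(i) {
    uid <- remaining$user_id[i]
    successful_installation(uploads$time[uploads$user_id == uid],
                            remaining$registration[i], params)
  }, logical(1))
  if (nrow(remaining) == 0L) ok_install <- logical(0)
  excluded <- rbind(excluded,
                    data.frame(user_id = remaining$user_id[!ok_install],
                               reason = rep("failed_installation",
                                            sum(!ok_install))))
  included <- remaining[ok_install, , drop = FALSE]
  rownames(included) <- NULL
  list(included = included,
       excluded = excluded,
       counts = c(total = nrow(users),
                  missing_demographics = sum(miss),
                  failed_installation = sum(!ok_install),
                  included = nrow(included)))
}

#' Build the per-user, per-stream retention table
#'
#' Produces exactly one right-censored survival record per included user
#' and data stream (passive, active), ordered by user then stream. A
#' user with no uploads at all on a stream is still given a record: the
#' silence clock runs from registration.
#'
#' @param users Data frame of included users (`user_id`, `registration`,
#'   `platform`, `occupation`, ...), e.g. the `included` element of
#'   [apply_exclusions()], or a `synthetic_cohort` object (in which case
#'   `uploads` is taken from the cohort and demographically incomplete
#'   users are dropped).
#' @param uploads Data frame `user_id`, `stream`, `time`.
#' @param window A [study_window()] (or a cutoff `Date`).
#' @param params A [retention_params()] object.
#' @return Data frame `user_id`, `stream`, `duration_days`, `event`,
#'   `platform`, `occupation`.
#' @export
build_retention_table <- function(users, uploads = NULL, window,
                                  params = retention_params()) {
  if (inherits(users, "synthetic_cohort")) {
    cohort <- users
    if (is.null(uploads)) uploads <- cohort$uploads
    if (missing(window)) window <- cohort$config$study_cutoff
    users <- cohort$users
    users <- users[!is.na(users$platform) & !is.na(users$occupation), ,
                   drop = FALSE]
  }
  stopifnot(is.data.frame(users), is.data.frame(uploads))
  if (inherits(window, "study_window")) window <- window$cutoff
  cutoff <- as.Date(window)
  streams <- c("active", "passive")  # alphabetical, for deterministic order
  users <- users[order(users$user_id), , drop = FALSE]
  n <- nrow(users)
  if (n == 0L) {
    return(data.frame(user_id = character(0), stream = character(0),
                      duration_days = integer(0), event = integer(0),
                      platform = character(0), occupation = character(0)))
  }
  # pre-split upload days by user and stream for speed
  reg <- users$registration[match(uploads$user_id, users$user_id)]
  day <- floor(as.numeric(difftime(uploads$time, reg, units = "days")))
  keep <- !is.na(day)
  key <- paste(uploads$user_id[keep], uploads$stream[keep], sep = "\r")
  day_by_key <- split(as.integer(day[keep]), key)

  horizon <- as.integer(floor(as.numeric(difftime(cutoff, users$registration,
                                                  units = "days"))))
  if (any(horizon < 0)) {
    stop("some registrations fall after the cutoff", call. = FALSE)
  }
  nrec <- 2L * n
  duration <- event <- integer(nrec)
  rec_user <- rec_stream <- rec_platform <- rec_occupation <- character(nrec)
  idx <- 0L
  for (i in seq_len(n)) {
    for (s in streams) {
      d <- day_by_key[[paste(users$user_id[i], s, sep = "\r")]]
      if (is.null(d)) d <- integer(0)
      if (length(d)) {
        if (is.unsorted(d, strictly = TRUE)) d <- sort(unique(d))
        if (d[1L] < 0) stop("uploads precede registration", call. = FALSE)
      }
      ct <- churn_scan(d, horizon[i], params$gap_days, params$churn_anchor)
      idx <- idx + 1L
      duration[idx] <- ct$duration_days
      event[idx] <- ct$event
      rec_user[idx] <- users$user_id[i]
      rec_stream[idx] <- s
      rec_platform[idx] <- as.character(users$platform[i])
      rec_occupation[idx] <- as.character(users$occupation[i])
    }
  }
  res <- data.frame(user_id = rec_user, stream = rec_stream,
                    duration_days = duration, event = event,
                    platform = rec_platform, occupation = rec_occupation)
  res <- res[order(res$user_id, res$stream), ]
  rownames(res) <- NULL
  res
}
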