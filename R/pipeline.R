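# CSV readers/writers for the pipeline's on-disk interchange formats.
# Every stage round-trips through plain CSV so each intermediate is
# independently inspectable and regenerable.

#' Read a GPS fix log
#'
#' Expects columns `user_id,timestamp,lat,lon` with ISO-8601 timestamps
#' (offset suffix `+HH:MM`, `+HHMM` or `Z`).
#'
#' @param path CSV file path.
#' @return Data frame `user_id`, `time` (POSIXct, UTC-based), `lat`,
#'   `lon`.
#' @export
read_gps_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_cols(d, c("user_id", "timestamp", "lat", "lon"), path)
  data.frame(user_id = as.character(d$user_id),
             time = parse_iso8601(d$timestamp),
             lat = as.numeric(d$lat),
             lon = as.numeric(d$lon))
}

#' Read a workplace registry
#'
#' Expects columns `user_id,workplace_id,lat,lon`; at most 5 rows per
#' user.
#'
#' @param path CSV file path.
#' @return Data frame as read, validated.
#' @export
read_workplaces <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_cols(d, c("user_id", "workplace_id", "lat", "lon"), path)
  over <- table(d$user_id) > 5
  if (any(over)) {
    stop("more than 5 workplaces registered for user(s): ",
         paste(names(which(over)), collapse = ", "), call. = FALSE)
  }
  d
}

#' Read an upload-event log
#'
#' Expects columns `user_id,stream,timestamp` with `stream` in
#' `{passive, active}`.
#'
#' @param path CSV file path.
#' @return Data frame `user_id`, `stream`, `time` (`Date`).
#' @export
read_upload_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_cols(d, c("user_id", "stream", "timestamp"), path)
  if (!all(d$stream %in% c("passive", "active"))) {
    stop("stream must be 'passive' or 'active' in ", path, call. = FALSE)
  }
  data.frame(user_id = as.character(d$user_id),
             stream = d$stream,
             time = as.Date(substr(d$timestamp, 1, 10)))
}

#' Read a user registration table
#'
#' Expects columns
#' `user_id,registration_date,platform,occupation,age,gender`; empty
#' strings are treated as missing demographics.
#'
#' @param path CSV file path.
#' @return Data frame `user_id`, `registration` (`Date`), `platform`,
#'   `occupation`, `age`, `gender`.
#' @export
read_registrations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need_cols(d, c("user_id", "registration_date", "platform", "occupation",
                 "age", "gender"), path)
  data.frame(user_id = as.character(d$user_id),
             registration = as.Date(d$registration_date),
             platform = d$platform,
             occupation = d$occupation,
             age = as.numeric(d$age),
             gender = d$gender)
}

need_cols <- function(d, cols, path) {
  miss <- setdiff(cols, names(d))
  if (length(miss)) {
    stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path,
         call. = FALSE)
  }
  invisible(d)
}

parse_iso8601 <- function(x) {
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  if (anyNA(out)) {
    stop("unparseable ISO-8601 timestamp(s), e.g. ",
         x[which(is.na(out))[1L]], call. = FALSE)
  }
  out
}

format_iso8601 <- function(t, tz = "Asia/Taipei") {
  s <- format(t, "%Y-%m-%dT%H:%M:%S%z", tz = tz)
  sub("([+-]\\d{2})(\\d{2})$", "\\1:\\2", s)
}

write_csv_plain <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a cohort and write its CSV inputs
#'
#' Wraps [generate_cohort()] and writes the pipeline's input files to
#' `out_dir`: `users.csv`, `uploads.csv`, `ground_truth.csv`, and (when
#' traces are generated) `workplaces.csv` and `gps.csv`.
#'
#' @param config A [cohort_config()] (or a path to a run-config JSON,
#'   see [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
run_simulate <- function(config = cohort_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)$cohort
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  coh <- generate_cohort(config)
  paths <- c(users = file.path(out_dir, "users.csv"),
             uploads = file.path(out_dir, "uploads.csv"),
             ground_truth = file.path(out_dir, "ground_truth.csv"))
  u <- coh$users
  write_csv_plain(data.frame(user_id = u$user_id,
                             registration_date = format(u$registration),
                             platform = u$platform,
                             occupation = u$occupation,
                             age = u$age, gender = u$gender),
                  paths[["users"]])
  write_csv_plain(data.frame(user_id = coh$uploads$user_id,
                             stream = coh$uploads$stream,
                             timestamp = format(coh$uploads$time)),
                  paths[["uploads"]])
  gt <- coh$ground_truth
  write_csv_plain(data.frame(user_id = gt$user_id, stream = gt$stream,
                             true_churn_day = gt$true_churn_day),
                  paths[["ground_truth"]])
  if (!is.null(coh$gps)) {
    paths[["workplaces"]] <- file.path(out_dir, "workplaces.csv")
    paths[["gps"]] <- file.path(out_dir, "gps.csv")
    write_csv_plain(coh$workplaces, paths[["workplaces"]])
    write_csv_plain(data.frame(user_id = coh$gps$user_id,
                               timestamp = format_iso8601(coh$gps$time),
                               lat = sprintf("%.6f", coh$gps$lat),
                               lon = sprintf("%.6f", coh$gps$lon)),
                    paths[["gps"]])
  }
  invisible(paths)
}

#' Detect work sessions and daily hours from GPS logs
#'
#' Runs [detect_sessions()] per user and [daily_work_hours()] on the
#' result, writing `sessions.csv`
#' (`user_id,start,end,duration_min,open_at_end`) and `daily.csv`
#' (`user_id,date,total_hours,scheduled_hours,overtime_hours`).
#'
#' @param gps_csv,workplaces_csv Input file paths.
#' @param out_dir Output directory.
#' @param params A [geofence_params()].
#' @param scheduled_hours Passed to [daily_work_hours()].
#' @param tz Local timezone for calendar-day splitting.
#' @return Invisibly, the named vector of written file paths.
#' @export
run_workhours <- function(gps_csv, workplaces_csv, out_dir,
                          params = geofence_params(), scheduled_hours = 8,
                          tz = "Asia/Taipei") {
  require_file(gps_csv)
  require_file(workplaces_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gps <- read_gps_log(gps_csv)
  wp <- read_workplaces(workplaces_csv)
  sessions <- lapply(split(gps, gps$user_id), function(tr) {
    tr <- tr[order(tr$time), , drop = FALSE]
    detect_sessions(tr, wp[wp$user_id == tr$user_id[1L], , drop = FALSE],
                    params)
  })
  sessions <- do.call(rbind, sessions)
  rownames(sessions) <- NULL
  daily <- daily_work_hours(sessions, scheduled_hours = scheduled_hours,
                            tz = tz)
  paths <- c(sessions = file.path(out_dir, "sessions.csv"),
             daily = file.path(out_dir, "daily.csv"))
  write_csv_plain(data.frame(user_id = sessions$user_id,
                             start = format_iso8601(sessions$start, tz),
                             end = format_iso8601(sessions$end, tz),
                             duration_min = sessions$duration_min,
                             open_at_end = sessions$open_at_end),
                  paths[["sessions"]])
  write_csv_plain(data.frame(user_id = daily$user_id,
                             date = format(daily$date),
                             total_hours = round(daily$total_hours, 4),
                             scheduled_hours = daily$scheduled_hours,
                             overtime_hours = round(daily$overtime_hours, 4)),
                  paths[["daily"]])
  invisible(paths)
}

#' Build the retention table from upload and registration logs
#'
#' Applies the enrolment exclusions and the churn rule, writing
#' `retention.csv`
#' (`user_id,stream,duration_days,event,platform,occupation`) and
#' `exclusions.csv` (`user_id,reason`).
#'
#' @param uploads_csv,users_csv Input file paths.
#' @param out_dir Output directory.
#' @param window A [study_window()] or cutoff `Date`.
#' @param params A [retention_params()].
#' @return Invisibly, the named vector of written file paths.
#' @export
run_retention <- function(uploads_csv, users_csv, out_dir,
                          window = study_window("2018-08-01", "2019-03-31"),
                          params = retention_params()) {
  require_file(uploads_csv)
  require_file(users_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  uploads <- read_upload_log(uploads_csv)
  users <- read_registrations(users_csv)
  excl <- apply_exclusions(users, uploads, params)
  rt <- build_retention_table(excl$included, uploads, window, params)
  paths <- c(retention = file.path(out_dir, "retention.csv"),
             exclusions = file.path(out_dir, "exclusions.csv"))
  write_csv_plain(rt, paths[["retention"]])
  write_csv_plain(excl$excluded, paths[["exclusions"]])
  invisible(paths)
}

#' Survival analysis of a retention table
#'
#' Fits the study's models ([fit_retention_models()]) and writes:
#' one Kaplan-Meier CSV per stream and per stream-by-platform stratum
#' (`time,at_risk,events,survival,greenwood_se`), `logrank.csv`,
#' `cox_<stream>.json` reports, and a two-panel survival figure
#' `survival_curves.png`.
#'
#' @param retention_csv Input retention table path.
#' @param out_dir Output directory.
#' @param univariable,ties Passed to [fit_retention_models()].
#' @return Invisibly, the fitted `"retention_models"` object.
#' @export
run_survive <- function(retention_csv, out_dir, univariable = FALSE,
                        ties = "efron") {
  require_file(retention_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rt <- utils::read.csv(retention_csv, stringsAsFactors = FALSE)
  if (nrow(rt) == 0L) {
    stop("no records in the retention table", call. = FALSE)
  }
  fits <- fit_retention_models(rt, univariable = univariable, ties = ties)
  for (nm in names(fits$km)) {
    write_km_csv(fits$km[[nm]], file.path(out_dir, paste0("km_", nm, ".csv")))
  }
  for (nm in names(fits$km_platform)) {
    write_km_csv(fits$km_platform[[nm]],
                 file.path(out_dir,
                           paste0("km_", sub("\\.", "_", nm), ".csv")))
  }
  lr <- do.call(rbind, lapply(names(fits$logrank), function(nm) {
    x <- fits$logrank[[nm]]
    data.frame(comparison = nm, chi_square = x$chi_square, df = x$df,
               p_value = x$p_value)
  }))
  write_csv_plain(lr, file.path(out_dir, "logrank.csv"))
  for (s in names(fits$cox)) {
    jsonlite::write_json(cox_report(fits$cox[[s]], fits$univariable),
                         file.path(out_dir, paste0("cox_", s, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  plot_survival_figure(fits, file.path(out_dir, "survival_curves.png"))
  invisible(fits)
}

write_km_csv <- function(km, path) {
  write_csv_plain(data.frame(time = km$time, at_risk = km$n_risk,
                             events = km$n_event, survival = km$surv,
                             greenwood_se = km$std_err),
                  path)
}

cox_report <- function(fit, univariable) {
  one <- function(f) {
    list(coefficients = as.list(f$coefficients),
         hazard_ratios = as.list(f$hazard_ratio),
         ci_lower = as.list(f$ci_lower),
         ci_upper = as.list(f$ci_upper),
         p_values = as.list(f$p_value),
         ties = f$ties, iterations = f$iter, converged = f$converged,
         n = f$n, n_events = f$n_events)
  }
  if (univariable) lapply(fit, one) else one(fit)
}

plot_survival_figure <- function(fits, path) {
  grDevices::png(path, width = 1400, height = 600, res = 120)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  plot(fits$km$passive, conf_int = FALSE, col = "steelblue",
       main = "Retention by data stream")
  lines(fits$km$active, col = "firebrick")
  graphics::legend("topright", legend = names(fits$km), bty = "n",
                   col = c("steelblue", "firebrick"), lty = 1)
  pf_names <- names(fits$km_platform)
  cols <- rep(c("darkgreen", "orange", "steelblue", "firebrick"),
              length.out = length(pf_names))
  first <- TRUE
  for (i in seq_along(pf_names)) {
    if (first) {
      plot(fits$km_platform[[i]], conf_int = FALSE, col = cols[i],
           main = "Retention by stream and platform")
      first <- FALSE
    } else {
      lines(fits$km_platform[[i]], col = cols[i])
    }
  }
  graphics::legend("topright", legend = pf_names, bty = "n",
                   col = cols[seq_along(pf_names)], lty = 1)
  invisible(path)
}

#' Assemble a markdown run report
#'
#' Collects the intermediates written by the other stages from
#' `run_dir` into a single `report.md`: cohort composition, survival
#' readouts at one week and one month per group, log-rank tests, and a
#' hazard-ratio table.
#'
#' @param run_dir Directory holding the outputs of [run_retention()]
#'   and [run_survive()].
#' @return Invisibly, the report path.
#' @export
run_report <- function(run_dir) {
  rt_path <- file.path(run_dir, "retention.csv")
  require_file(rt_path)
  rt <- utils::read.csv(rt_path, stringsAsFactors = FALSE)
  lines <- c("# App user retention report", "")
  lines <- c(lines, "## Cohort", "",
             sprintf("- %d users, %d retention records",
                     length(unique(rt$user_id)), nrow(rt)),
             sprintf("- platforms: %s",
                     paste(sprintf("%s (%d)",
                                   names(table(rt$platform[rt$stream ==
                                                             "passive"])),
                                   table(rt$platform[rt$stream == "passive"])),
                           collapse = ", ")), "")
  lines <- c(lines, "## Retention at one week / one month", "")
  for (s in unique(rt$stream)) {
    d <- rt[rt$stream == s, ]
    km <- kaplan_meier(d$duration_days, d$event)
    lines <- c(lines,
               sprintf("- %s: S(7) = %.1f%%, S(28) = %.1f%%", s,
                       100 * survival_at(km, 7), 100 * survival_at(km, 28)))
    for (pf in sort(unique(d$platform))) {
      dp <- d[d$platform == pf, ]
      kmp <- kaplan_meier(dp$duration_days, dp$event)
      lines <- c(lines,
                 sprintf("  - %s/%s: S(7) = %.1f%%, S(28) = %.1f%%", s, pf,
                         100 * survival_at(kmp, 7),
                         100 * survival_at(kmp, 28)))
    }
  }
  lr_path <- file.path(run_dir, "logrank.csv")
  if (file.exists(lr_path)) {
    lr <- utils::read.csv(lr_path)
    lines <- c(lines, "", "## Log-rank tests", "",
               sprintf("- %s: chi-square = %.3f, p = %.3g",
                       lr$comparison, lr$chi_square, lr$p_value))
  }
  cox_files <- list.files(run_dir, pattern = "^cox_.*\\.json$",
                          full.names = TRUE)
  if (length(cox_files)) {
    lines <- c(lines, "", "## Cox proportional-hazards model", "",
               "| Stream | Factor | HR (95% CI) | p |",
               "|---|---|---|---|")
    for (f in cox_files) {
      s <- sub("^cox_(.*)\\.json$", "\\1", basename(f))
      rep_ <- jsonlite::read_json(f)
      reps <- if (!is.null(rep_$hazard_ratios)) list(rep_) else rep_
      for (r in reps) {
        for (nm in names(r$hazard_ratios)) {
          lines <- c(lines,
                     sprintf("| %s | %s | %.3f (%.3f-%.3f) | %.3g |",
                             s, nm, r$hazard_ratios[[nm]],
                             r$ci_lower[[nm]], r$ci_upper[[nm]],
                             r$p_values[[nm]]))
        }
      }
    }
  }
  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

require_file <- function(path) {
  if (!file.exists(path)) {
    stop("required input not found: ", path,
         " (run the upstream stage first)", call. = FALSE)
  }
  invisible(path)
}

#' Read and validate a run-config JSON file
#'
#' The run config carries the seed, the simulation parameters and the
#' stage parameters for a pipeline run; its field layout is described
#' by the schema shipped at
#' `system.file("schema", "run-config-schema.json", package = "dwellsurv")`.
#' Unknown fields are an error, as are out-of-range values (checked by
#' the constructors the fields are passed to).
#'
#' @param path JSON file path.
#' @return A list with elements `cohort` (a [cohort_config()]),
#'   `geofence` (a [geofence_params()]), `retention` (a
#'   [retention_params()]), `window` (a [study_window()]), and `seed`.
#' @export
read_run_config <- function(path) {
  require_file(path)
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("run config is not valid JSON: ",
                         conditionMessage(e), call. = FALSE)
                  })
  allowed <- c("seed", "n_users", "missing_demographics", "platform_mix",
               "occupation_mix", "active_cadence", "trace_days",
               "registration_window", "study_cutoff", "churn_hazards",
               "geofence", "retention")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown run-config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ca <- list()
  for (f in c("n_users", "missing_demographics", "active_cadence",
              "trace_days", "study_cutoff", "seed")) {
    if (!is.null(cfg[[f]])) ca[[f]] <- cfg[[f]]
  }
  if (!is.null(cfg$registration_window)) {
    ca$registration_window <- as.Date(unlist(cfg$registration_window))
  }
  if (!is.null(cfg$platform_mix)) ca$platform_mix <- unlist(cfg$platform_mix)
  if (!is.null(cfg$occupation_mix)) {
    ca$occupation_mix <- unlist(cfg$occupation_mix)
  }
  if (!is.null(cfg$churn_hazards)) {
    ca$churn_hazards <- lapply(cfg$churn_hazards, function(s) {
      lapply(s, as.numeric)
    })
  }
  cohort <- do.call(cohort_config, ca)
  geofence <- do.call(geofence_params, as.list(cfg$geofence))
  retention <- do.call(retention_params, as.list(cfg$retention))
  window <- study_window(cohort$registration_window[1], cohort$study_cutoff)
  list(cohort = cohort, geofence = geofence, retention = retention,
       window = window, seed = cohort$seed)
}
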