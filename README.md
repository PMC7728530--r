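# dwellsurv

Survival analysis of mobile-app user retention, built around the data a
workplace-tracking app actually produces: GPS fix streams sampled every
10 minutes (passive data) and monthly mental-health survey submissions
(active data). The package is aimed at digital-phenotyping and mHealth
researchers who want to quantify *how long users keep generating data*
and which factors (operating system, occupation) change that.

It provides four things:

1. **Geofence work-hour detection.** A work session opens when fixes
   stay inside a 1-km radius of a registered workplace (up to five per
   user) for a consecutive 30 minutes, with the start assigned
   retroactively to the first in-range fix, and closes after 30
   consecutive out-of-range (or missing) minutes. Daily totals are split
   at local midnight and signed overtime is `total − scheduled`.
2. **Churn-event construction.** User retention ends on the first date
   of a 28-day period without any upload; records are right-censored at
   the study cutoff. Installation succeeds only if something was
   uploaded in the first 28 days after registration.
3. **Survival statistics from first principles.** Kaplan-Meier with
   Greenwood variance, the two-sample log-rank test, and Cox
   proportional-hazards regression (Newton-Raphson on the log partial
   likelihood, Efron or Breslow ties, Wald inference). The `survival`
   package is used only as an independent cross-check in the test suite.
4. **A calibrated synthetic cohort generator** with known
   piecewise-exponential churn hazards (days 0–7, 7–28, 28+), exact
   covariate margins, daily passive uploads, monthly or daily active
   events, and commuter GPS traces — so the whole pipeline is testable
   end to end without access to raw telemetry.

## The model

For durations \(T_i\) (whole days from registration) with event
indicator \(\delta_i\) (1 = churn observed), the Kaplan-Meier estimate
is the product limit

\[ \hat S(t) = \prod_{t_j \le t} \Bigl(1 - \frac{d_j}{n_j}\Bigr), \qquad
\widehat{\mathrm{Var}}\,\hat S(t) = \hat S(t)^2 \sum_{t_j \le t}
\frac{d_j}{n_j (n_j - d_j)}, \]

the log-rank statistic accumulates \(O-E\) over pooled event times with
hypergeometric variance, and the Cox model assumes
\(\lambda(t \mid x) = \lambda_0(t) e^{x^\top \beta}\) with \(e^\beta\)
reported as a hazard ratio. The synthetic generator draws continuous
churn times from piecewise-constant hazards \(\lambda_1\) (days 0–7)
and \(\lambda_2\) (days 7–28) obtained in closed form from week/month
retention anchors: \(\lambda_1 = -\log S_7 / 7\),
\(\lambda_2 = -\log(S_{28}/S_7)/21\).

## Worked example

Simulate the default cohort (342 users, Android share 0.318,
piecewise-exponential churn hazards calibrated per stream and platform),
build the retention table, and fit the study models:

```r
library(dwellsurv)
coh  <- generate_cohort(cohort_config(seed = 2018))
rt   <- build_retention_table(coh)
fits <- fit_retention_models(rt)
fits
#> Retention survival analysis (per-stream Cox joint fits)
#>
#> passive stream: n = 342, events = 322, S(7) = 46.2%, S(28) = 26.0%
#> active stream: n = 342, events = 342, S(7) = 21.3%, S(28) = 2.3%
#>
#> Hazard ratios (95% CI):
#>   passive  ios       HR = 2.367 (1.844-3.037), p = 0.000
#>   passive  resident  HR = 0.824 (0.656-1.036), p = 0.097
#>   active   ios       HR = 0.379 (0.297-0.483), p = 0.000
#>   active   resident  HR = 0.876 (0.702-1.092), p = 0.240
#>
#> Log-rank tests:
#>   stream             chi-square = 109.146, p = 0.000
#>   passive_platform   chi-square = 47.972, p = 0.000
#>   active_platform    chi-square = 60.051, p = 0.000
```

Passive data retain roughly 46% of users after one week and 26% after
one month in this draw; active (survey) retention decays much faster,
and iOS more than doubles the passive churn hazard — the structure the
generator was calibrated to. `plot(fits$km$passive)` draws the step
curve with Greenwood bands.

The geofence side works the same way from a GPS trace:

```r
tr <- generate_trace("u1", as.Date("2018-09-03"))
wp <- data.frame(workplace_id = "w1", lat = 25.041, lon = 121.535)
s  <- detect_sessions(tr, wp)
s
#>   user_id               start                 end duration_min open_at_end
#> 1      u1 2018-09-03 08:50:00 2018-09-03 18:20:00          570       FALSE
daily_work_hours(s, scheduled_hours = 8)
#>   user_id       date total_hours scheduled_hours overtime_hours
#> 1      u1 2018-09-03         9.5               8            1.5
```

A command-line front end over the same functions ships at
`system.file("cli", "dwellsurv", package = "dwellsurv")` with
subcommands `simulate`, `workhours`, `retention`, `survive` and
`report`; every stage reads and writes plain CSV so intermediates are
independently inspectable.

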