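#' Outcomes modelled by the package
#' @export
OUTCOMES <- c("steps", "light", "mvpa", "sedentary")

# default piecewise levels (per analysis period) for each outcome, on the
# scale reported by the device: steps/day and minutes/day
.default_levels <- list(
  steps     = c(9641, 6769, 7299),
  light     = c(239, 197, 216),
  mvpa      = c(47.6, 35.4, 39.9),
  sedentary = c(659, 712, 678)
)

# weekday pattern (Mon..Sun), sums to zero; activity peaks midweek and dips
# on weekends, sedentary time moves the other way
.weekday_pattern <- c(0.3, 0.4, 0.3, 0.2, 0.1, -0.6, -0.7)

.default_weekday_effects <- function(amplitude = 0.05) {
  lapply(.default_levels, function(lv) {
    eff <- .weekday_pattern * amplitude * lv[1]
    if (lv[2] > lv[1]) eff <- -eff  # sedentary-type outcome: invert
    eff
  })
}

#' Configuration for the synthetic wearable cohort
#'
#' Defines the ground-truth data-generating process: a population piecewise
#' trend per outcome with calendar break dates, participant-level random
#' intercepts, weekday seasonality, Gaussian day-level noise, a wear
#' compliance model, heart-rate artifacts, and nightly sleep episodes that
#' usually span midnight.
#'
#' @param n_participants number of simulated participants.
#' @param start_date,end_date study window (defaults: one year,
#'   2019-11-01 to 2020-10-30).
#' @param break_dates calendar dates at which the population level changes;
#'   must lie strictly inside the window.
#' @param outcome_trends named list (one per outcome) of data frames with
#'   columns `start` (Date of segment start), `level` (segment mean at its
#'   start) and `slope` (change per day within the segment). Default:
#'   piecewise-constant segments at the package's reference period means
#'   with segment starts at `start_date` and `break_dates`.
#' @param sd_between named numeric: between-participant SD of the random
#'   intercept, per outcome, in outcome units.
#' @param sd_within named numeric: day-level residual SD per outcome.
#' @param weekday_effects named list of 7 additive offsets (Mon..Sun, outcome
#'   units) each summing to 0. Default amplitude is 5% of the first-segment
#'   level.
#' @param compliance list controlling wear behaviour:
#'   `p_never` (fraction of participants who never reach a valid day),
#'   `beta_shape1`/`beta_shape2` (Beta distribution of each regular
#'   participant's daily probability of a compliant day), `p_daily`
#'   (optional fixed daily compliance probability overriding the Beta draw),
#'   `daywear_compliant_mean`/`_sd`/`_range` and
#'   `daywear_noncompliant_mean`/`_sd`/`_range` (clipped-Gaussian day-wear
#'   targets, minutes).
#' @param hr_artifact_rate fraction of emitted heart-rate minutes carrying an
#'   aphysiologic value (bpm < 50 or > 200).
#' @param sleep_minutes_mean,sleep_minutes_sd nightly main-sleep duration
#'   (minutes), clipped to `[120, 600]`.
#' @param sleep_onset_mean,sleep_onset_sd sleep onset in minutes after the
#'   night's midnight-to-midnight day start (default 1425 = 23:45), so that
#'   most episodes cross midnight.
#' @param dropout_after optional Date: compliance forced to zero afterwards
#'   (supports testing the minimum-valid-days filter).
#' @param seed integer default seed for generation.
#'
#' @return an object of class `synthetic_config` (a validated list).
#' @seealso [generate_daily_records()], [generate_minute_streams()],
#'   [simulate_cohort()]
#' @export
synthetic_config <- function(n_participants = 315,
                             start_date = as.Date("2019-11-01"),
                             end_date = as.Date("2020-10-30"),
                             break_dates = as.Date(c("2020-03-13", "2020-06-13")),
                             outcome_trends = NULL,
                             sd_between = c(steps = 1800, light = 35,
                                            mvpa = 12, sedentary = 70),
                             sd_within = c(steps = 2500, light = 50,
                                           mvpa = 18, sedentary = 90),
                             weekday_effects = NULL,
                             compliance = list(),
                             hr_artifact_rate = 0.02,
                             sleep_minutes_mean = 367,
                             sleep_minutes_sd = 67,
                             sleep_onset_mean = 1425,
                             sleep_onset_sd = 45,
                             dropout_after = NULL,
                             seed = 20191101L) {
  start_date <- as_date_strict(start_date, "start_date")
  end_date <- as_date_strict(end_date, "end_date")
  break_dates <- sort(as_date_strict(break_dates, "break_dates"))

  if (is.null(outcome_trends)) {
    starts <- c(start_date, break_dates)
    outcome_trends <- lapply(.default_levels, function(lv) {
      if (length(lv) != length(starts))
        lv <- rep_len(lv, length(starts))
      data.frame(start = starts, level = lv, slope = 0)
    })
  }
  if (is.null(weekday_effects)) {
    weekday_effects <- lapply(outcome_trends, function(tr) {
      eff <- .weekday_pattern * 0.05 * tr$level[1]
      if (nrow(tr) > 1 && tr$level[2] > tr$level[1]) eff <- -eff
      eff
    })
  }

  comp_defaults <- list(
    p_never = 8 / 315,
    beta_shape1 = 2.6, beta_shape2 = 2.0,
    p_daily = NULL,
    daywear_compliant_mean = 850, daywear_compliant_sd = 90,
    daywear_compliant_range = c(620, 1000),
    daywear_noncompliant_mean = 350, daywear_noncompliant_sd = 120,
    daywear_noncompliant_range = c(0, 580)
  )
  compliance <- utils::modifyList(comp_defaults, compliance)

  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    start_date = start_date, end_date = end_date,
    break_dates = break_dates,
    outcome_trends = outcome_trends,
    sd_between = sd_between, sd_within = sd_within,
    weekday_effects = weekday_effects,
    compliance = compliance,
    hr_artifact_rate = hr_artifact_rate,
    sleep_minutes_mean = sleep_minutes_mean,
    sleep_minutes_sd = sleep_minutes_sd,
    sleep_onset_mean = sleep_onset_mean,
    sleep_onset_sd = sleep_onset_sd,
    dropout_after = if (!is.null(dropout_after)) as_date_strict(dropout_after),
    seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

#' @rdname synthetic_config
#' @param cfg a `synthetic_config` object.
#' @export
validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_participants < 0) stop("n_participants must be >= 0")
  if (!(cfg$end_date > cfg$start_date)) stop("end_date must be after start_date")
  if (length(cfg$break_dates) &&
      (any(cfg$break_dates <= cfg$start_date) || any(cfg$break_dates >= cfg$end_date)))
    stop("break_dates must lie strictly inside (start_date, end_date)")
  for (o in names(cfg$outcome_trends)) {
    tr <- cfg$outcome_trends[[o]]
    if (!all(c("start", "level", "slope") %in% names(tr)))
      stop("outcome_trends[['", o, "']] needs columns start, level, slope")
    if (is.unsorted(as.integer(tr$start), strictly = TRUE))
      stop("segment starts for '", o, "' must be strictly increasing")
  }
  if (any(cfg$sd_between < 0) || any(cfg$sd_within < 0))
    stop("all SDs must be >= 0")
  for (o in names(cfg$weekday_effects)) {
    w <- cfg$weekday_effects[[o]]
    if (length(w) != 7L) stop("weekday_effects[['", o, "']] must have 7 entries")
    if (abs(sum(w)) > 1e-9) stop("weekday_effects for '", o, "' must sum to 0")
  }
  pc <- cfg$compliance
  probs <- c(pc$p_never, pc$p_daily %||% 0.5)
  if (any(probs < 0 | probs > 1)) stop("compliance probabilities must lie in [0, 1]")
  if (cfg$hr_artifact_rate < 0 || cfg$hr_artifact_rate >= 1)
    stop("hr_artifact_rate must lie in [0, 1)")
  if (cfg$sleep_minutes_sd < 0) stop("sleep_minutes_sd must be >= 0")
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  %d participants, %s .. %s (%d days)\n", x$n_participants,
              x$start_date, x$end_date,
              as.integer(x$end_date - x$start_date) + 1L))
  cat("  break dates:", paste(format(x$break_dates), collapse = ", "), "\n")
  cat("  outcomes:", paste(names(x$outcome_trends), collapse = ", "), "\n")
  invisible(x)
}

#' Expected population level of an outcome on a date
#'
#' The deterministic part of the generating model: the level of the trend
#' segment containing `date`, plus `slope * (days since segment start)`,
#' plus the weekday offset for `date`'s day of week.
#'
#' @param config a [synthetic_config()].
#' @param outcome one of `"steps"`, `"light"`, `"mvpa"`, `"sedentary"`.
#' @param date Date vector within the study window.
#' @return numeric vector of expected outcome levels.
#' @export
population_trend <- function(config, outcome, date) {
  validate_synthetic_config(config)
  if (!outcome %in% names(config$outcome_trends))
    stop("unknown outcome '", outcome, "'")
  date <- as_date_strict(date)
  if (any(date < config$start_date | date > config$end_date))
    stop("date outside the study window")
  tr <- config$outcome_trends[[outcome]]
  seg <- findInterval(as.integer(date), as.integer(tr$start))
  stopifnot(all(seg >= 1L))
  lev <- tr$level[seg] + tr$slope[seg] * as.numeric(date - tr$start[seg])
  lev + config$weekday_effects[[outcome]][iso_weekday(date)]
}
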