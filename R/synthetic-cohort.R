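#' Generate daily activity records with known ground truth
#'
#' Draws, for every participant and study day, the four daily outcomes from
#' the additive Gaussian model
#' \deqn{y_{it} = trend(t) + b_i + e_{it},}
#' with one standardised random intercept per participant shared across
#' outcomes and scaled by the outcome's `sd_between`, and independent
#' day-level noise with SD `sd_within`. Steps are rounded to nonnegative
#' integers; minute outcomes are rounded and clipped to `[0, 1440]`, and the
#' four intensity classes are rescaled if their sum would exceed 1440
#' minutes. MVPA is split into "fairly active" (75%) and "very active" (25%)
#' minutes so that the records round-trip through the daily-summary CSV
#' dialect.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list with elements `daily` (data.frame: participant_id, date,
#'   steps, sedentary_min, light_min, moderate_min, vigorous_min, mvpa_min)
#'   and `ground_truth` (break dates, per-outcome segment levels, and the
#'   per-participant random intercepts).
#' @export
generate_daily_records <- function(config, seed = config$seed) {
  validate_synthetic_config(config)
  n <- config$n_participants
  dates <- seq(config$start_date, config$end_date, by = "day")
  ids <- sprintf("P%04d", seq_len(n))

  with_seed(seed, {
    b_raw <- rnorm(n)  # shared standardised intercept, scaled per outcome
    grid <- data.table::CJ(participant_id = ids, date = dates, sorted = TRUE)
    out <- grid
    vals <- list()
    for (o in OUTCOMES) {
      mu <- population_trend(config, o, grid$date)
      b <- config$sd_between[[o]] * b_raw[match(grid$participant_id, ids)]
      e <- rnorm(nrow(grid), 0, config$sd_within[[o]])
      vals[[o]] <- mu + b + e
    }
    steps <- pmax(0, round(vals$steps))
    light <- pmin(1440, pmax(0, round(vals$light)))
    mvpa <- pmin(1440, pmax(0, round(vals$mvpa)))
    sedentary <- pmin(1440, pmax(0, round(vals$sedentary)))
    # keep intensity classes within the day: rescale proportionally if needed
    tot <- light + mvpa + sedentary
    over <- tot > 1440
    if (any(over)) {
      f <- 1440 / tot[over]
      light[over] <- floor(light[over] * f)
      mvpa[over] <- floor(mvpa[over] * f)
      sedentary[over] <- floor(sedentary[over] * f)
    }
    moderate <- round(0.75 * mvpa)
    vigorous <- mvpa - moderate
    daily <- data.frame(
      participant_id = grid$participant_id, date = grid$date,
      steps = as.integer(steps), sedentary_min = as.integer(sedentary),
      light_min = as.integer(light), moderate_min = as.integer(moderate),
      vigorous_min = as.integer(vigorous), mvpa_min = as.integer(mvpa),
      stringsAsFactors = FALSE
    )
    truth <- list(
      break_dates = config$break_dates,
      segment_levels = lapply(config$outcome_trends, function(tr) tr$level),
      intercepts = data.frame(participant_id = ids, b_raw = b_raw,
                              stringsAsFactors = FALSE),
      seed = seed
    )
    list(daily = daily, ground_truth = truth)
  })
}

#' Draw the per-participant wear schedule
#'
#' Each regular participant gets a daily compliance probability from a Beta
#' distribution (or the fixed `p_daily` if configured); a `p_never` fraction
#' of participants never achieve a compliant day. Each participant-day is
#' then compliant (day-wear target drawn from the compliant clipped-Gaussian
#' distribution, always >= 600 minutes) or not (< 600). Nightly main-sleep
#' episodes are drawn with onset around the configured clock time so that
#' most episodes span midnight; nights one day before the window are
#' included so the first study day has attributable sleep.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return list: `schedule` (participant_id, date, compliant,
#'   target_day_wear, sleep_min), `sleep` (participant_id, onset, offset),
#'   `participants` (participant_id, p_daily, never_wearer,
#'   true_valid_days, analyzed_true).
#' @export
draw_wear_schedule <- function(config, seed = config$seed + 1L) {
  validate_synthetic_config(config)
  n <- config$n_participants
  dates <- seq(config$start_date, config$end_date, by = "day")
  nd <- length(dates)
  ids <- sprintf("P%04d", seq_len(n))
  pc <- config$compliance

  with_seed(seed, {
    never <- runif(n) < pc$p_never
    p_i <- if (!is.null(pc$p_daily)) rep(pc$p_daily, n)
           else rbeta(n, pc$beta_shape1, pc$beta_shape2)
    p_i[never] <- 0

    grid <- data.table::CJ(participant_id = ids, date = dates, sorted = TRUE)
    p_day <- p_i[match(grid$participant_id, ids)]
    if (!is.null(config$dropout_after))
      p_day[grid$date > config$dropout_after] <- 0
    compliant <- runif(nrow(grid)) < p_day
    target <- numeric(nrow(grid))
    target[compliant] <- round(rnorm_clip(sum(compliant),
      pc$daywear_compliant_mean, pc$daywear_compliant_sd,
      pc$daywear_compliant_range[1], pc$daywear_compliant_range[2]))
    target[!compliant] <- round(rnorm_clip(sum(!compliant),
      pc$daywear_noncompliant_mean, pc$daywear_noncompliant_sd,
      pc$daywear_noncompliant_range[1], pc$daywear_noncompliant_range[2]))

    # one main sleep episode per night, night of (start_date - 1) included
    nights <- seq(config$start_date - 1L, config$end_date, by = "day")
    ngrid <- data.table::CJ(participant_id = ids, night = nights, sorted = TRUE)
    onset_min <- rnorm(nrow(ngrid), config$sleep_onset_mean, config$sleep_onset_sd)
    dur <- rnorm_clip(nrow(ngrid), config$sleep_minutes_mean,
                      config$sleep_minutes_sd, 120, 600)
    onset <- as.POSIXct(as.numeric(as.POSIXct(ngrid$night, tz = "UTC")) +
                          round(onset_min) * 60, tz = "UTC", origin = "1970-01-01")
    offset <- onset + round(dur) * 60
    sleep <- data.frame(participant_id = ngrid$participant_id,
                        onset = onset, offset = offset,
                        stringsAsFactors = FALSE)

    # calendar-day sleep minutes implied by the episodes, inside the window
    smap <- sleep_minutes_per_day(sleep)
    sched <- data.table::as.data.table(grid)
    sched[, compliant := compliant]
    sched[, target_day_wear := as.integer(target)]
    smap_dt <- data.table::as.data.table(smap)
    sched <- merge(sched, smap_dt, by = c("participant_id", "date"),
                   all.x = TRUE)
    sched[is.na(sleep_minutes), sleep_minutes := 0L]
    data.table::setnames(sched, "sleep_minutes", "sleep_min")
    # a day's wear plus its attributed sleep cannot exceed the 1440-minute
    # day; clamp the target so minute emission can realise it exactly
    sched[, target_day_wear := pmin(target_day_wear, 1440L - sleep_min)]

    vd <- sched[, list(true_valid_days = sum(target_day_wear >= 600L)),
                by = participant_id]
    parts <- data.frame(participant_id = ids, p_daily = p_i,
                        never_wearer = never, stringsAsFactors = FALSE)
    parts <- merge(parts, as.data.frame(vd), by = "participant_id")
    parts$analyzed_true <- parts$true_valid_days >= 250L
    list(schedule = as.data.frame(sched), sleep = sleep, participants = parts)
  })
}

#' Generate minute-level heart-rate streams consistent with a wear schedule
#'
#' For every participant-day, emits heart-rate minutes so that after
#' aphysiologic-value removal and calendar-day sleep subtraction the day's
#' day-wear lands on the scheduled target (within the 1440-minute day
#' capacity): all sleep minutes attributed to the date carry a valid reading
#' (the device records heart rate during sleep), `target_day_wear` further
#' valid minutes are placed in waking slots, and artifact minutes (bpm < 50
#' or > 200) are added in remaining slots at `hr_artifact_rate` of emitted
#' minutes (binomial count per day).
#'
#' @param daily daily records from [generate_daily_records()] (used for the
#'   participant/date grid).
#' @param config a [synthetic_config()].
#' @param seed RNG seed; defaults to `config$seed + 2`.
#' @param schedule optional result of [draw_wear_schedule()]; drawn fresh
#'   (from `config$seed + 1`) when omitted so that the full generation is
#'   reproducible from `config$seed` alone.
#' @return list: `minutes` (participant_id, timestamp, bpm), `sleep`
#'   (participant_id, onset, offset), `schedule` (as in
#'   [draw_wear_schedule()]).
#' @export
generate_minute_streams <- function(daily, config, seed = config$seed + 2L,
                                    schedule = NULL) {
  validate_synthetic_config(config)
  if (is.null(schedule)) schedule <- draw_wear_schedule(config)
  sched <- data.table::as.data.table(schedule$schedule)
  keep <- unique(daily$participant_id)
  sched <- sched[participant_id %in% keep]

  # minute-of-day slots slept, per participant-date (from the episodes)
  slept <- sleep_minute_slots(schedule$sleep)

  r <- config$hr_artifact_rate
  with_seed(seed, {
    res_id <- vector("list", nrow(sched))
    res_min <- vector("list", nrow(sched))
    res_bpm <- vector("list", nrow(sched))
    day0 <- as.integer(sched$date) * 1440L  # minutes since epoch at 00:00
    key <- paste(sched$participant_id, sched$date)
    for (row in seq_len(nrow(sched))) {
      sleep_slots <- slept[[key[row]]] %||% integer(0)
      wake_slots <- setdiff(0:1439, sleep_slots)
      w <- min(sched$target_day_wear[row], length(wake_slots))
      valid_slots <- c(sleep_slots, sort(sample(wake_slots, w)))
      n_valid <- length(valid_slots)
      n_art <- 0L
      if (r > 0 && n_valid > 0) {
        n_art <- rbinom(1L, size = as.integer(round(n_valid / (1 - r))), prob = r)
        free <- setdiff(0:1439, valid_slots)
        n_art <- min(n_art, length(free))
        art_slots <- sort(sample(free, n_art))
      } else art_slots <- integer(0)
      slots <- c(valid_slots, art_slots)
      bpm <- integer(length(slots))
      bpm[seq_len(n_valid)] <- pmin(199L, pmax(51L, as.integer(round(rnorm(n_valid, 75, 10)))))
      if (n_art > 0) {
        lo <- runif(n_art) < 0.5
        bpm[n_valid + seq_len(n_art)] <- ifelse(lo,
          sample(30:49, n_art, replace = TRUE),
          sample(201:220, n_art, replace = TRUE))
      }
      o <- order(slots)
      res_id[[row]] <- rep.int(sched$participant_id[row], length(slots))
      res_min[[row]] <- day0[row] + slots[o]
      res_bpm[[row]] <- bpm[o]
    }
    minutes <- data.frame(
      participant_id = unlist(res_id, use.names = FALSE) %||% character(0),
      timestamp = as.POSIXct(60 * as.numeric(unlist(res_min, use.names = FALSE) %||% numeric(0)),
                             tz = "UTC", origin = "1970-01-01"),
      bpm = as.integer(unlist(res_bpm, use.names = FALSE) %||% integer(0)),
      stringsAsFactors = FALSE
    )
    sleep_out <- schedule$sleep[schedule$sleep$participant_id %in% keep, ,
                                drop = FALSE]
    list(minutes = minutes, sleep = sleep_out,
         schedule = as.data.frame(sched))
  })
}

# minute-of-day slots (0..1439) covered by sleep, as a named list keyed by
# "participant date"
sleep_minute_slots <- function(sleep) {
  if (nrow(sleep) == 0L) return(list())
  a <- floor(as.numeric(sleep$onset) / 60)
  b <- ceiling(as.numeric(sleep$offset) / 60) - 1
  out <- new.env(parent = emptyenv())
  for (k in seq_along(a)) {
    mins <- a[k]:b[k]
    d <- mins %/% 1440
    for (dd in unique(d)) {
      ky <- paste(sleep$participant_id[k],
                  as.Date(dd, origin = "1970-01-01"))
      slots <- mins[d == dd] %% 1440
      prev <- if (!is.null(out[[ky]])) out[[ky]] else integer(0)
      out[[ky]] <- union(prev, slots)
    }
  }
  as.list(out)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper that draws daily records, the wear schedule, and
#' (optionally) the minute-level heart-rate streams, and returns the merged
#' ground truth. With `minute_level = FALSE` the schedule's day-wear targets
#' stand in for the validated wear assessment (see
#' [schedule_to_assessments()]), which makes large many-seed experiments
#' cheap while exercising the identical downstream chain.
#'
#' @param config a [synthetic_config()].
#' @param minute_level emit minute heart-rate streams and sleep episodes?
#' @param seed overall seed; defaults to `config$seed`.
#' @return list: `daily`, `schedule`, `participants`, `ground_truth`, and
#'   (minute_level only) `minutes`, `sleep`.
#' @export
simulate_cohort <- function(config, minute_level = FALSE, seed = config$seed) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  gen <- generate_daily_records(cfg, seed = cfg$seed)
  ws <- draw_wear_schedule(cfg, seed = cfg$seed + 1L)
  out <- list(daily = gen$daily, schedule = ws$schedule,
              participants = ws$participants,
              ground_truth = c(gen$ground_truth,
                               list(analyzed_true = ws$participants$participant_id[
                                 ws$participants$analyzed_true])))
  if (minute_level) {
    ms <- generate_minute_streams(gen$daily, cfg, seed = cfg$seed + 2L,
                                  schedule = ws)
    out$minutes <- ms$minutes
    out$sleep <- ms$sleep
  }
  out
}

#' Convert a wear schedule into wear assessments
#'
#' Produces the `WearAssessment` table the minute-level validation chain
#' would yield (day-wear equal to the scheduled target), for fast
#' large-cohort experiments.
#'
#' @param schedule the `schedule` element of [draw_wear_schedule()].
#' @param params a [validation_params()].
#' @return data.frame as returned by [assess_days()].
#' @export
schedule_to_assessments <- function(schedule, params = validation_params()) {
  data.frame(
    participant_id = schedule$participant_id,
    date = schedule$date,
    wear_minutes = pmin(1440L, schedule$target_day_wear + schedule$sleep_min),
    sleep_minutes = schedule$sleep_min,
    day_wear_minutes = schedule$target_day_wear,
    is_valid_day = schedule$target_day_wear >= params$valid_day_threshold,
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic cohort as Fitabase-style CSV fixtures
#'
#' Writes the three CSV dialects consumed by [read_minute_hr()],
#' [read_daily_summary()] and [read_sleep()]; round-trips losslessly.
#'
#' @param sim result of [simulate_cohort()] with `minute_level = TRUE`.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_fixture_set <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(minute_hr = file.path(dir, "heartrate_minutes.csv"),
             daily = file.path(dir, "daily_activity.csv"),
             sleep = file.path(dir, "sleep_episodes.csv"))
  if (is.null(sim$minutes) || is.null(sim$sleep))
    stop("write_fixture_set needs a minute-level simulation ",
         "(simulate_cohort(..., minute_level = TRUE))")
  write_minute_hr(sim$minutes, paths[["minute_hr"]])
  write_daily_summary(sim$daily, paths[["daily"]])
  write_sleep(sim$sleep, paths[["sleep"]])
  paths
}
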