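# CSV dialects: simplified Fitabase-like exports with ISO 8601 timestamps.
# minute HR:      Id,Time,Value            (Time = YYYY-MM-DD HH:MM:SS)
# daily summary:  Id,ActivityDate,TotalSteps,SedentaryMinutes,
#                 LightlyActiveMinutes,FairlyActiveMinutes,VeryActiveMinutes
# sleep:          Id,StartTime,EndTime

.check_header <- function(dt, expected, path) {
  if (!identical(names(dt), expected))
    stop("unexpected header in ", path, "\n  expected: ",
         paste(expected, collapse = ","), "\n  found:    ",
         paste(names(dt), collapse = ","), call. = FALSE)
}

#' Read a minute-level heart-rate CSV
#'
#' Expects the header `Id,Time,Value` with ISO `YYYY-MM-DD HH:MM:SS`
#' timestamps. Malformed rows (unparseable time or non-numeric value) are
#' skipped with a warning; the skipped count is attached as attribute
#' `n_skipped`. A missing or wrong header is a hard error.
#'
#' @param path CSV file path.
#' @return data.frame: participant_id, timestamp (POSIXct), bpm.
#' @export
read_minute_hr <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE)
  .check_header(dt, c("Id", "Time", "Value"), path)
  ts <- as.POSIXct(dt$Time, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  bpm <- suppressWarnings(as.numeric(dt$Value))
  bad <- is.na(ts) | is.na(bpm)
  warn_count(sum(bad), paste0("malformed rows skipped in ", basename(path)))
  out <- data.frame(participant_id = dt$Id[!bad], timestamp = ts[!bad],
                    bpm = bpm[!bad], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' @rdname read_minute_hr
#' @param records data.frame as returned by the corresponding reader.
#' @export
write_minute_hr <- function(records, path) {
  data.table::fwrite(data.table::data.table(
    Id = records$participant_id,
    Time = format(records$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    Value = records$bpm), path)
  invisible(path)
}

#' Read a daily activity summary CSV
#'
#' Expects the header `Id,ActivityDate,TotalSteps,SedentaryMinutes,`
#' `LightlyActiveMinutes,FairlyActiveMinutes,VeryActiveMinutes`. MVPA is
#' derived as fairly-active plus very-active minutes. Rows with negative
#' steps, minute fields outside `[0, 1440]`, or unparseable values are
#' rejected with a warning (count in attribute `n_skipped`).
#'
#' @param path CSV file path.
#' @return data.frame: participant_id, date, steps, sedentary_min,
#'   light_min, moderate_min, vigorous_min, mvpa_min.
#' @export
read_daily_summary <- function(path) {
  expected <- c("Id", "ActivityDate", "TotalSteps", "SedentaryMinutes",
                "LightlyActiveMinutes", "FairlyActiveMinutes",
                "VeryActiveMinutes")
  dt <- data.table::fread(path, colClasses = "character", header = TRUE)
  .check_header(dt, expected, path)
  date <- suppressWarnings(as.Date(dt$ActivityDate, format = "%Y-%m-%d"))
  num <- lapply(dt[, 3:7], function(x) suppressWarnings(as.numeric(x)))
  mins <- do.call(cbind, num[2:5])
  bad <- is.na(date) | Reduce(`|`, lapply(num, is.na)) |
    num$TotalSteps < 0 | apply(mins < 0 | mins > 1440, 1, any)
  warn_count(sum(bad), paste0("rows rejected in ", basename(path),
                              " (missing/out-of-range values)"))
  keep <- !bad
  out <- data.frame(
    participant_id = dt$Id[keep], date = date[keep],
    steps = as.integer(num$TotalSteps[keep]),
    sedentary_min = as.integer(num$SedentaryMinutes[keep]),
    light_min = as.integer(num$LightlyActiveMinutes[keep]),
    moderate_min = as.integer(num$FairlyActiveMinutes[keep]),
    vigorous_min = as.integer(num$VeryActiveMinutes[keep]),
    stringsAsFactors = FALSE
  )
  out$mvpa_min <- out$moderate_min + out$vigorous_min
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' @rdname read_daily_summary
#' @param records data.frame as returned by the corresponding reader.
#' @export
write_daily_summary <- function(records, path) {
  data.table::fwrite(data.table::data.table(
    Id = records$participant_id,
    ActivityDate = format(records$date, "%Y-%m-%d"),
    TotalSteps = records$steps,
    SedentaryMinutes = records$sedentary_min,
    LightlyActiveMinutes = records$light_min,
    FairlyActiveMinutes = records$moderate_min,
    VeryActiveMinutes = records$vigorous_min), path)
  invisible(path)
}

#' Read a sleep-episode CSV
#'
#' Expects the header `Id,StartTime,EndTime` (ISO timestamps). Episodes
#' with unparseable times or `EndTime <= StartTime` are rejected with a
#' warning (count in attribute `n_skipped`).
#'
#' @param path CSV file path.
#' @return data.frame: participant_id, onset, offset (POSIXct).
#' @export
read_sleep <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE)
  .check_header(dt, c("Id", "StartTime", "EndTime"), path)
  onset <- as.POSIXct(dt$StartTime, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  offset <- as.POSIXct(dt$EndTime, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  bad <- is.na(onset) | is.na(offset) | offset <= onset
  warn_count(sum(bad), paste0("sleep rows rejected in ", basename(path)))
  out <- data.frame(participant_id = dt$Id[!bad], onset = onset[!bad],
                    offset = offset[!bad], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' @rdname read_sleep
#' @param records data.frame as returned by the corresponding reader.
#' @export
write_sleep <- function(records, path) {
  data.table::fwrite(data.table::data.table(
    Id = records$participant_id,
    StartTime = format(records$onset, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    EndTime = format(records$offset, "%Y-%m-%d %H:%M:%S", tz = "UTC")), path)
  invisible(path)
}

#' Run configuration
#'
#' Bundles input paths, validation thresholds, period and segmentation
#' settings for [run_pipeline()]. Can be read from a JSON (or YAML) file
#' with [read_run_config()].
#'
#' @param minute_hr,sleep,daily input CSV paths.
#' @param params a [validation_params()].
#' @param periods a [period_definition()].
#' @param spec a [segment_spec()].
#' @param outcomes subset of `c("steps", "light", "mvpa", "sedentary")`.
#' @param out_dir output directory for artifacts.
#' @param seed RNG seed for the bootstrap intervals.
#' @param min_contributors per-date minimum for the cohort series.
#' @param ci_boot number of bootstrap replicates for break-date intervals
#'   (0 disables interval estimation).
#' @return object of class `run_config`.
#' @export
run_config <- function(minute_hr, sleep, daily,
                       params = validation_params(),
                       periods = period_definition(),
                       spec = segment_spec(),
                       outcomes = OUTCOMES,
                       out_dir = tempfile("wearbreaks_run"),
                       seed = 1L, min_contributors = 1L, ci_boot = 200L) {
  for (p in c(minute_hr, sleep, daily))
    if (!file.exists(p)) stop("input file does not exist: ", p, call. = FALSE)
  if (!all(outcomes %in% OUTCOMES))
    stop("outcomes must be a subset of ", paste(OUTCOMES, collapse = ", "))
  structure(list(minute_hr = minute_hr, sleep = sleep, daily = daily,
                 params = params, periods = periods, spec = spec,
                 outcomes = outcomes, out_dir = out_dir,
                 seed = as.integer(seed),
                 min_contributors = as.integer(min_contributors),
                 ci_boot = as.integer(ci_boot)),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON (`.json`) or YAML (`.yml`/`.yaml`) configuration file;
#'   recognised keys mirror the arguments of `run_config()`, with
#'   `params`, `periods` and `spec` given as nested objects.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(validation_params, c(
    as.list(raw$params)[intersect(names(raw$params),
                                  c("hr_lower", "hr_upper",
                                    "valid_day_threshold", "min_valid_days"))],
    if (!is.null(raw$params$study_window))
      list(study_window = as.Date(unlist(raw$params$study_window)))) %||% list())
  periods <- do.call(period_definition, c(
    if (!is.null(raw$periods$boundaries))
      list(boundaries = as.Date(unlist(raw$periods$boundaries))),
    if (!is.null(raw$periods$window))
      list(window = as.Date(unlist(raw$periods$window))),
    if (!is.null(raw$periods$labels)) list(labels = unlist(raw$periods$labels))) %||%
      list())
  spec <- do.call(segment_spec, as.list(raw$spec)[intersect(names(raw$spec),
    c("design", "min_segment_frac", "m_max"))] %||% list())
  run_config(minute_hr = raw$minute_hr, sleep = raw$sleep, daily = raw$daily,
             params = params, periods = periods, spec = spec,
             outcomes = raw$outcomes %||% OUTCOMES,
             out_dir = raw$out_dir %||% tempfile("wearbreaks_run"),
             seed = raw$seed %||% 1L,
             min_contributors = raw$min_contributors %||% 1L,
             ci_boot = raw$ci_boot %||% 200L)
}
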