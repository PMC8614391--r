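#' Validation parameters for wear-time cleaning
#'
#' Thresholds for the heart-rate-arbitrated cleaning chain: aphysiologic
#' heart-rate bounds, the minimum day-wear for a valid day, the minimum
#' number of valid days for an analysable participant, and the study window.
#'
#' @param hr_lower,hr_upper plausible heart-rate range (bpm); readings
#'   outside `[hr_lower, hr_upper]` are treated as aphysiologic and removed.
#' @param valid_day_threshold minimum day-wear minutes (wear minus
#'   calendar-day sleep) for a day to count as valid.
#' @param min_valid_days minimum number of valid days inside the study
#'   window for a participant to be analysed.
#' @param study_window length-2 Date vector `[start, end]`.
#' @return object of class `validation_params`.
#' @export
validation_params <- function(hr_lower = 50, hr_upper = 200,
                              valid_day_threshold = 600,
                              min_valid_days = 250,
                              study_window = as.Date(c("2019-11-01",
                                                       "2020-10-30"))) {
  stopifnot_scalar_num(hr_lower, "hr_lower", 1)
  stopifnot_scalar_num(hr_upper, "hr_upper", hr_lower + 1)
  stopifnot_scalar_num(valid_day_threshold, "valid_day_threshold", 1, 1440)
  stopifnot_scalar_num(min_valid_days, "min_valid_days", 1)
  study_window <- as_date_strict(study_window, "study_window")
  if (length(study_window) != 2L || study_window[2] <= study_window[1])
    stop("study_window must be two increasing dates")
  ndays <- as.integer(study_window[2] - study_window[1]) + 1L
  if (min_valid_days > ndays)
    stop("min_valid_days exceeds the study window length (", ndays, " days)")
  structure(list(hr_lower = hr_lower, hr_upper = hr_upper,
                 valid_day_threshold = as.integer(valid_day_threshold),
                 min_valid_days = as.integer(min_valid_days),
                 study_window = study_window),
            class = "validation_params")
}

#' Remove aphysiologic heart-rate readings
#'
#' Keeps exactly the records with `hr_lower <= bpm <= hr_upper`. Records
#' with nonpositive or missing bpm are malformed (not aphysiologic) and are
#' dropped with a warning; their count is attached as attribute
#' `n_malformed`. Input order is preserved.
#'
#' @param records data.frame with columns participant_id, timestamp, bpm.
#' @param params a [validation_params()].
#' @return the filtered records (attributes: `n_malformed`, `n_aphysiologic`).
#' @export
clean_heart_rate <- function(records, params = validation_params()) {
  stopifnot(all(c("participant_id", "timestamp", "bpm") %in% names(records)))
  bpm <- records$bpm
  malformed <- is.na(bpm) | bpm <= 0
  warn_count(sum(malformed), "malformed heart-rate records dropped (bpm <= 0 or missing)")
  ok <- !malformed & bpm >= params$hr_lower & bpm <= params$hr_upper
  out <- records[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- sum(malformed)
  attr(out, "n_aphysiologic") <- sum(!malformed & !ok)
  out
}

#' Wear minutes per participant-day
#'
#' Counts, per participant and local calendar date, the distinct clock
#' minutes containing at least one valid heart-rate reading; this count is
#' the proxy for device wear time. Sub-minute duplicates collapse to one
#' minute; the result never exceeds 1440.
#'
#' @param records cleaned heart-rate records (see [clean_heart_rate()]).
#' @return data.frame: participant_id, date, wear_minutes.
#' @export
wear_minutes_per_day <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(participant_id = character(0),
                      date = as.Date(character(0)),
                      wear_minutes = integer(0)))
  dt <- data.table::data.table(
    participant_id = records$participant_id,
    minute = floor(as.numeric(records$timestamp) / 60)
  )
  dt <- unique(dt)
  dt[, date := as.Date(minute %/% 1440, origin = "1970-01-01")]
  res <- dt[, list(wear_minutes = .N), by = list(participant_id, date)]
  data.table::setkey(res, participant_id, date)
  as.data.frame(res)
}

#' Sleep minutes per participant-calendar-day
#'
#' Clips each sleep episode to calendar-day boundaries (half-open
#' `[00:00, 24:00)`; a minute belongs to the day containing its start) and
#' attributes its minutes to the corresponding dates, so an overnight
#' episode contributes to two days. Overlapping episodes are unioned, never
#' double-counted. Episodes with `offset <= onset` are rejected with a
#' warning.
#'
#' @param episodes data.frame: participant_id, onset, offset (POSIXct).
#' @return data.frame: participant_id, date, sleep_minutes (each <= 1440).
#' @export
sleep_minutes_per_day <- function(episodes) {
  empty <- data.frame(participant_id = character(0),
                      date = as.Date(character(0)),
                      sleep_minutes = integer(0))
  if (nrow(episodes) == 0L) return(empty)
  bad <- !(episodes$offset > episodes$onset)
  warn_count(sum(bad), "sleep episodes rejected (offset <= onset)")
  ep <- episodes[!bad, , drop = FALSE]
  if (nrow(ep) == 0L) return(empty)

  a <- floor(as.numeric(ep$onset) / 60)
  b <- ceiling(as.numeric(ep$offset) / 60) - 1  # any minute overlapping sleep
  dt <- data.table::data.table(participant_id = ep$participant_id, a = a, b = b)
  # union intervals per participant before counting
  data.table::setorder(dt, participant_id, a)
  dt[, grp := cumsum(a > data.table::shift(cummax(b), fill = -Inf) + 1),
     by = participant_id]
  merged <- dt[, list(a = min(a), b = max(b)), by = list(participant_id, grp)]
  # split merged runs at day boundaries and count per date
  out <- merged[, {
    mins <- seq.int(a, b)
    d <- mins %/% 1440L
    tab <- tabulate(d - min(d) + 1L)
    keep <- tab > 0
    list(day = (min(d) + which(keep) - 1L), n = tab[keep])
  }, by = list(participant_id, grp)]
  res <- out[, list(sleep_minutes = sum(n)), by = list(participant_id, day)]
  res[, date := as.Date(day, origin = "1970-01-01")]
  res[, sleep_minutes := pmin(1440L, as.integer(sleep_minutes))]
  res <- res[, list(participant_id, date, sleep_minutes)]
  data.table::setkey(res, participant_id, date)
  as.data.frame(res)
}

#' Assess participant-days for validity
#'
#' Joins the wear and sleep maps on (participant, date) and computes
#' `day_wear = max(0, wear - sleep)`; a day is valid when day-wear meets
#' `valid_day_threshold`. Dates with wear data but no sleep data use sleep
#' 0; dates present only in the sleep map are emitted with wear 0 and are
#' invalid.
#'
#' @param wear output of [wear_minutes_per_day()].
#' @param sleep output of [sleep_minutes_per_day()].
#' @param params a [validation_params()].
#' @return data.frame: participant_id, date, wear_minutes, sleep_minutes,
#'   day_wear_minutes, is_valid_day.
#' @export
assess_days <- function(wear, sleep, params = validation_params()) {
  w <- data.table::as.data.table(wear)
  s <- data.table::as.data.table(sleep)
  m <- merge(w, s, by = c("participant_id", "date"), all = TRUE)
  if (!"wear_minutes" %in% names(m)) m[, wear_minutes := integer(0)]
  if (!"sleep_minutes" %in% names(m)) m[, sleep_minutes := integer(0)]
  m[is.na(wear_minutes), wear_minutes := 0L]
  m[is.na(sleep_minutes), sleep_minutes := 0L]
  m[, day_wear_minutes := pmax(0L, wear_minutes - sleep_minutes)]
  m[, is_valid_day := day_wear_minutes >= params$valid_day_threshold]
  data.table::setkey(m, participant_id, date)
  as.data.frame(m)
}

#' Select analysable participants
#'
#' A participant is included when the number of valid days inside the study
#' window reaches `min_valid_days`; per-participant counts are returned for
#' audit.
#'
#' @param assessments output of [assess_days()].
#' @param params a [validation_params()].
#' @return data.frame: participant_id, valid_days, included.
#' @export
select_participants <- function(assessments, params = validation_params()) {
  a <- data.table::as.data.table(assessments)
  a <- a[date >= params$study_window[1] & date <= params$study_window[2]]
  res <- a[, list(valid_days = sum(is_valid_day)), by = participant_id]
  res[, included := valid_days >= params$min_valid_days]
  data.table::setkey(res, participant_id)
  as.data.frame(res)
}
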