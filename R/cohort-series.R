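.outcome_columns <- c(steps = "steps", light = "light_min",
                      mvpa = "mvpa_min", sedentary = "sedentary_min")

#' Build the cohort mean time series of an outcome
#'
#' For each date, the unweighted mean of the outcome over participant-days
#' that are flagged valid and belong to included participants; dates with
#' fewer than `min_contributors` contributing participant-days are dropped.
#'
#' @param daily daily activity records (see [read_daily_summary()] or
#'   [generate_daily_records()]).
#' @param assessments output of [assess_days()].
#' @param outcome one of `"steps"`, `"light"`, `"mvpa"`, `"sedentary"`.
#' @param min_contributors minimum contributing participant-days per date.
#' @param included optional character vector of participant ids to restrict
#'   to (typically `participant_id[included]` from [select_participants()]);
#'   `NULL` keeps all participants present in `assessments`.
#' @return a `cohort_series` data.frame: date, mean, n (ordered by date,
#'   strictly increasing), with the outcome name as attribute `outcome`.
#' @export
build_series <- function(daily, assessments, outcome, min_contributors = 1L,
                         included = NULL) {
  if (!outcome %in% names(.outcome_columns))
    stop("unknown outcome '", outcome, "'; expected one of ",
         paste(names(.outcome_columns), collapse = ", "))
  col <- .outcome_columns[[outcome]]
  d <- data.table::as.data.table(daily)
  a <- data.table::as.data.table(assessments)[is_valid_day == TRUE,
                                              list(participant_id, date)]
  if (!is.null(included)) a <- a[participant_id %in% included]
  m <- merge(d, a, by = c("participant_id", "date"))
  res <- m[, list(mean = mean(.SD[[1]]), n = .N), by = date, .SDcols = col]
  res <- res[n >= min_contributors]
  data.table::setorder(res, date)
  out <- as.data.frame(res)
  attr(out, "outcome") <- outcome
  class(out) <- c("cohort_series", "data.frame")
  out
}

#' @export
print.cohort_series <- function(x, ...) {
  cat(sprintf("<cohort_series: %s> %d dates, %s .. %s, median n = %d\n",
              attr(x, "outcome") %||% "?", nrow(x),
              format(min(x$date)), format(max(x$date)),
              as.integer(median(x$n))))
  NextMethod()
}

#' Define contiguous analysis periods
#'
#' Splits the study window into labelled, contiguous, non-overlapping
#' periods at the given boundary dates (each boundary starts a new period).
#'
#' @param boundaries Dates at which a new period begins (strictly inside
#'   the window). Default: 2020-03-01 and 2020-06-01, the first days of the
#'   initial-mitigation and partial-reopening phases.
#' @param window length-2 Date vector, the study window.
#' @param labels period labels, length `length(boundaries) + 1`.
#' @return a `period_definition` data.frame: label, start, end.
#' @export
period_definition <- function(boundaries = as.Date(c("2020-03-01", "2020-06-01")),
                              window = as.Date(c("2019-11-01", "2020-10-30")),
                              labels = NULL) {
  window <- as_date_strict(window, "window")
  boundaries <- sort(as_date_strict(boundaries, "boundaries"))
  if (any(boundaries <= window[1]) || any(boundaries > window[2]))
    stop("period boundaries must lie inside the study window")
  starts <- c(window[1], boundaries)
  ends <- c(boundaries - 1L, window[2])
  labels <- labels %||% paste0("P", seq_along(starts))
  stopifnot(length(labels) == length(starts))
  structure(data.frame(label = labels, start = starts, end = ends,
                       stringsAsFactors = FALSE),
            class = c("period_definition", "data.frame"))
}

#' Assign dates to analysis periods
#'
#' @param date Date vector.
#' @param periods a [period_definition()].
#' @return factor of period labels (levels in period order); errors if any
#'   date falls outside all periods.
#' @export
assign_period <- function(date, periods = period_definition()) {
  date <- as_date_strict(date)
  idx <- findInterval(as.integer(date), as.integer(periods$start))
  if (any(idx < 1L) || any(date > periods$end[pmax(idx, 1L)]))
    stop("date outside all defined periods: ",
         paste(format(date[idx < 1L | date > periods$end[pmax(idx, 1L)]][1]),
               collapse = ", "))
  factor(periods$label[idx], levels = periods$label)
}

#' Assemble participant-day observations for mixed-model inference
#'
#' Restricts daily records to valid days of included participants, attaches
#' the period label and (optionally) a participant-level group label.
#'
#' @inheritParams build_series
#' @param periods a [period_definition()].
#' @param groups optional data.frame participant_id, group.
#' @return data.frame: participant_id, date, period, value, (group).
#' @export
make_long_observations <- function(daily, assessments, outcome,
                                   periods = period_definition(),
                                   included = NULL, groups = NULL) {
  col <- .outcome_columns[[outcome]]
  if (is.null(col)) stop("unknown outcome '", outcome, "'")
  d <- data.table::as.data.table(daily)
  a <- data.table::as.data.table(assessments)[is_valid_day == TRUE,
                                              list(participant_id, date)]
  if (!is.null(included)) a <- a[participant_id %in% included]
  m <- merge(d, a, by = c("participant_id", "date"))
  m <- m[date >= min(periods$start) & date <= max(periods$end)]
  out <- data.frame(participant_id = m$participant_id, date = m$date,
                    period = assign_period(m$date, periods),
                    value = as.numeric(m[[col]]),
                    stringsAsFactors = FALSE)
  if (!is.null(groups))
    out$group <- groups$group[match(out$participant_id, groups$participant_id)]
  out
}
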