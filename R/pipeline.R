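#' Run the full analysis pipeline
#'
#' Executes the end-to-end chain on the configured inputs: heart-rate
#' cleaning, wear/sleep aggregation, day validity assessment, participant
#' selection, cohort series construction, structural-break detection with
#' bootstrap intervals, and between-period mixed-model contrasts, writing
#' all artifacts under `config$out_dir`:
#' \itemize{
#'   \item `audit_participants.csv` — per-participant valid days and flag;
#'   \item `series_<outcome>.csv` — the cohort series;
#'   \item `breaks_<outcome>.json` — the segmentation and intervals;
#'   \item `contrasts_<outcome>.csv` — the pairwise period contrasts;
#'   \item `run_report.json` — filter counts, version, config echo.
#' }
#' Any stage failure aborts with a stage-labelled error and removes partial
#' outputs. Re-running with identical inputs and seed reproduces identical
#' outputs.
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  if (created) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) tryCatch(expr, error = function(e) fail(name, e))
  emit <- function(path) { written <<- c(written, path); path }

  inputs <- stage("read", {
    list(hr = read_minute_hr(config$minute_hr),
         sleep = read_sleep(config$sleep),
         daily = read_daily_summary(config$daily))
  })
  evaluated_ids <- sort(unique(c(inputs$hr$participant_id,
                                 inputs$daily$participant_id,
                                 inputs$sleep$participant_id)))

  sel <- stage("validate", {
    clean <- clean_heart_rate(inputs$hr, config$params)
    wear <- wear_minutes_per_day(clean)
    slp <- sleep_minutes_per_day(inputs$sleep)
    assessments <- assess_days(wear, slp, config$params)
    selection <- select_participants(assessments, config$params)
    # participants with no assessable days at all count as zero valid days
    missing <- setdiff(evaluated_ids, selection$participant_id)
    if (length(missing))
      selection <- rbind(selection,
                         data.frame(participant_id = missing, valid_days = 0L,
                                    included = FALSE))
    selection <- selection[order(selection$participant_id), ]
    list(assessments = assessments, selection = selection)
  })
  included_ids <- sel$selection$participant_id[sel$selection$included]
  data.table::fwrite(sel$selection,
                     emit(file.path(out_dir, "audit_participants.csv")))

  results <- list()
  for (o in config$outcomes) {
    results[[o]] <- stage(paste0("analyze_", o), {
      series <- build_series(inputs$daily, sel$assessments, o,
                             min_contributors = config$min_contributors,
                             included = included_ids)
      data.table::fwrite(as.data.frame(series),
                         emit(file.path(out_dir, paste0("series_", o, ".csv"))))
      seg <- select_breaks(series, config$spec)
      ci <- NULL
      if (seg$m >= 1L && config$ci_boot > 0L)
        ci <- suppressWarnings(break_intervals(seg, n_boot = config$ci_boot,
                                               seed = config$seed))
      obs <- make_long_observations(inputs$daily, sel$assessments, o,
                                    periods = config$periods,
                                    included = included_ids)
      fit <- fit_random_intercept(obs)
      ctr <- pairwise_contrasts(fit)
      data.table::fwrite(as.data.frame(ctr),
                         emit(file.path(out_dir, paste0("contrasts_", o, ".csv"))))
      seg_json <- list(
        outcome = o, m = seg$m,
        breaks = seg$breaks,
        break_dates = if (!is.null(seg$break_dates)) format(seg$break_dates),
        exact_fit = seg$exact_fit,
        table = seg$table,
        intervals = if (!is.null(ci)) as.data.frame(ci),
        period_means = as.list(coef(fit)),
        sigma_b = sqrt(fit$sigma_b2), sigma = sqrt(fit$sigma2)
      )
      jsonlite::write_json(seg_json,
                           emit(file.path(out_dir, paste0("breaks_", o, ".json"))),
                           auto_unbox = TRUE, digits = NA, null = "null")
      list(series = series, segmentation = seg, intervals = ci,
           fit = fit, contrasts = ctr)
    })
  }

  counts <- list(
    evaluated = length(evaluated_ids),
    excluded_wear = sum(sel$selection$valid_days == 0L),
    excluded_days = sum(sel$selection$valid_days > 0L &
                          !sel$selection$included),
    analyzed = length(included_ids)
  )
  stopifnot(counts$evaluated ==
              counts$excluded_wear + counts$excluded_days + counts$analyzed)
  report <- list(
    counts = counts,
    outcomes = config$outcomes,
    version = as.character(packageVersion("wearbreaks")),
    config = list(
      minute_hr = config$minute_hr, sleep = config$sleep,
      daily = config$daily, seed = config$seed,
      valid_day_threshold = config$params$valid_day_threshold,
      min_valid_days = config$params$min_valid_days,
      hr_bounds = c(config$params$hr_lower, config$params$hr_upper),
      study_window = format(config$params$study_window),
      period_boundaries = format(config$periods$start[-1]),
      min_segment_frac = config$spec$min_segment_frac,
      m_max = config$spec$m_max
    )
  )
  jsonlite::write_json(report, emit(file.path(out_dir, "run_report.json")),
                       auto_unbox = TRUE, digits = NA)
  report$results <- results
  report$selection <- sel$selection
  invisible(report)
}

#' Quick rolling-mean plot of a cohort series
#'
#' Base-graphics convenience plot: the daily cohort mean with a centred
#' rolling mean overlaid and detected break dates marked.
#'
#' @param series a [build_series()] result.
#' @param window rolling window in days (default 7).
#' @param segmentation optional [select_breaks()] result; its break dates
#'   are drawn as vertical lines.
#' @param ... passed to [plot()].
#' @return invisibly, the series.
#' @export
plot_cohort_series <- function(series, window = 7L, segmentation = NULL, ...) {
  stopifnot(inherits(series, "cohort_series"))
  roll <- stats::filter(series$mean, rep(1 / window, window), sides = 2)
  plot(series$date, series$mean, type = "p", pch = 16, cex = 0.4,
       col = "grey60", xlab = "date",
       ylab = attr(series, "outcome") %||% "mean", ...)
  graphics::lines(series$date, roll, lwd = 2)
  if (!is.null(segmentation) && segmentation$m > 0 &&
      !is.null(segmentation$break_dates))
    graphics::abline(v = segmentation$break_dates, lty = 2, col = "red3")
  invisible(series)
}
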