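test_that("population trend reproduces segment levels, slopes and weekday offsets", {
  cfg <- tiny_config(weekday_effects = zero_weekday())
  # reference period-1 level on a date before the first break
  expect_equal(population_trend(cfg, "steps", as.Date("2019-12-01")), 9641)
  expect_equal(population_trend(cfg, "steps", as.Date("2020-04-01")), 6769)
  expect_equal(population_trend(cfg, "sedentary", as.Date("2020-07-01")), 678)

  # all-zero trend gives zero everywhere
  flat <- lapply(OUTCOMES, function(o)
    data.frame(start = as.Date("2019-11-01"), level = 0, slope = 0))
  names(flat) <- OUTCOMES
  cfg0 <- tiny_config(outcome_trends = flat, weekday_effects = zero_weekday())
  expect_equal(population_trend(cfg0, "mvpa",
                                seq(as.Date("2019-11-01"), by = "d", length = 20)),
               rep(0, 20))

  # linear within-segment slope: level 100, slope 10/day, 5 days in -> 150
  sl <- flat
  sl$steps <- data.frame(start = as.Date("2019-11-01"), level = 100, slope = 10)
  cfgs <- tiny_config(outcome_trends = sl, weekday_effects = zero_weekday(),
                      break_dates = as.Date(character(0)))
  expect_equal(population_trend(cfgs, "steps", as.Date("2019-11-06")), 150)

  # weekday effect is added for the date's day of week (2019-11-04 is a Monday)
  cfgw <- tiny_config()
  mon <- population_trend(cfgw, "steps", as.Date("2019-11-04"))
  expect_equal(mon - 9641, cfgw$weekday_effects$steps[1])

  expect_error(population_trend(cfg, "bogus", as.Date("2019-12-01")), "unknown outcome")
  expect_error(population_trend(cfg, "steps", as.Date("2021-05-01")), "outside")
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(start_date = "2020-01-01", end_date = "2019-01-01"),
               "end_date")
  expect_error(synthetic_config(break_dates = "2019-11-01"), "strictly inside")
  expect_error(synthetic_config(sd_within = c(steps = -1, light = 1, mvpa = 1,
                                              sedentary = 1)), "SDs")
  we <- zero_weekday(); we$steps <- rep(1, 7)
  expect_error(synthetic_config(weekday_effects = we), "sum to 0")
  expect_error(synthetic_config(hr_artifact_rate = 1.2), "hr_artifact_rate")
})

test_that("zero-noise daily records equal the population trend exactly", {
  cfg <- tiny_config(n = 3,
                     sd_between = c(steps = 0, light = 0, mvpa = 0, sedentary = 0),
                     sd_within = c(steps = 0, light = 0, mvpa = 0, sedentary = 0),
                     weekday_effects = zero_weekday())
  gen <- generate_daily_records(cfg)
  mu <- population_trend(cfg, "steps", gen$daily$date)
  expect_equal(gen$daily$steps, as.integer(round(mu)))
  mu_l <- population_trend(cfg, "light", gen$daily$date)
  expect_equal(gen$daily$light_min, as.integer(round(mu_l)))
  # derived field consistency
  expect_equal(gen$daily$mvpa_min, gen$daily$moderate_min + gen$daily$vigorous_min)
})

test_that("daily records respect bounds and recover the generating mean", {
  cfg <- synthetic_config(n_participants = 200, seed = 99,
                          sd_between = c(steps = 0, light = 0, mvpa = 0, sedentary = 0),
                          sd_within = c(steps = 1500, light = 30, mvpa = 10, sedentary = 60),
                          weekday_effects = zero_weekday())
  gen <- generate_daily_records(cfg)
  d <- gen$daily
  expect_true(all(d$steps >= 0))
  for (col in c("sedentary_min", "light_min", "moderate_min", "vigorous_min"))
    expect_true(all(d[[col]] >= 0 & d[[col]] <= 1440))
  expect_true(all(d$sedentary_min + d$light_min + d$moderate_min +
                    d$vigorous_min <= 1440))
  # Monte-Carlo: cohort mean on one date within 3 SE of the generating mean
  day <- as.Date("2019-12-10")
  obs <- d$steps[d$date == day]
  se <- 1500 / sqrt(length(obs))
  expect_lt(abs(mean(obs) - population_trend(cfg, "steps", day)), 3 * se)
})

test_that("generation is deterministic: same seed, identical output bytes", {
  cfg <- tiny_config(n = 3, seed = 42)
  s1 <- simulate_cohort(cfg, minute_level = TRUE)
  s2 <- simulate_cohort(cfg, minute_level = TRUE)
  expect_identical(s1, s2)
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture_set(s1, d1); write_fixture_set(s2, d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  # and a different seed changes the data
  s3 <- simulate_cohort(tiny_config(n = 3, seed = 43), minute_level = TRUE)
  expect_false(identical(s1$daily, s3$daily))
})

test_that("minute streams honour the wear schedule, artifact rate and sleep geometry", {
  cfg <- tiny_config(n = 5, seed = 11, hr_artifact_rate = 0.05,
                     compliance = list(p_daily = 1,
                                       daywear_compliant_mean = 700,
                                       daywear_compliant_sd = 0,
                                       daywear_compliant_range = c(700, 700)))
  sim <- simulate_cohort(cfg, minute_level = TRUE)

  # validated day-wear lands on the 700-minute target
  clean <- clean_heart_rate(sim$minutes)
  ass <- assess_days(wear_minutes_per_day(clean),
                     sleep_minutes_per_day(sim$sleep))
  m <- merge(ass, sim$schedule, by = c("participant_id", "date"))
  expect_true(all(abs(m$day_wear_minutes - m$target_day_wear) <= 5))
  expect_true(all(m$target_day_wear == 700))

  # artifact minutes: binomial 3-sigma band around the configured rate
  n_emit <- nrow(sim$minutes)
  n_art <- sum(sim$minutes$bpm < 50 | sim$minutes$bpm > 200)
  expect_lt(abs(n_art - 0.05 * n_emit), 3 * sqrt(n_emit * 0.05 * 0.95) + 3)

  # the majority of sleep episodes cross midnight
  crosses <- as.Date(sim$sleep$onset, tz = "UTC") !=
    as.Date(sim$sleep$offset - 1, tz = "UTC")
  expect_gte(mean(crosses), 0.5)
})

test_that("an overnight episode splits its minutes across the two calendar days", {
  ep <- data.frame(participant_id = "X",
                   onset = as.POSIXct("2020-01-01 23:00:00", tz = "UTC"),
                   offset = as.POSIXct("2020-01-02 07:00:00", tz = "UTC"))
  sm <- sleep_minutes_per_day(ep)
  expect_equal(sm$sleep_minutes[sm$date == as.Date("2020-01-01")], 60)
  expect_equal(sm$sleep_minutes[sm$date == as.Date("2020-01-02")], 420)
})

test_that("fixtures round-trip losslessly through the CSV readers", {
  cfg <- tiny_config(n = 5, seed = 21)
  sim <- simulate_cohort(cfg, minute_level = TRUE)
  dir <- tempfile()
  paths <- write_fixture_set(sim, dir)
  hr <- read_minute_hr(paths[["minute_hr"]])
  daily <- read_daily_summary(paths[["daily"]])
  slp <- read_sleep(paths[["sleep"]])
  expect_equal(hr$participant_id, sim$minutes$participant_id)
  expect_equal(as.numeric(hr$timestamp), as.numeric(sim$minutes$timestamp))
  expect_equal(hr$bpm, as.numeric(sim$minutes$bpm))
  expect_equal(daily[names(daily)], sim$daily[names(daily)],
               ignore_attr = TRUE)
  expect_equal(as.numeric(slp$onset), as.numeric(sim$sleep$onset))
  expect_equal(length(unique(hr$participant_id)), 5)

  # empty cohort writes valid headers-only files
  sim0 <- simulate_cohort(tiny_config(n = 0), minute_level = TRUE)
  dir0 <- tempfile()
  p0 <- write_fixture_set(sim0, dir0)
  expect_equal(nrow(read_minute_hr(p0[["minute_hr"]])), 0)
  expect_equal(nrow(read_daily_summary(p0[["daily"]])), 0)
})

test_that("between-participant variance of participant means recovers sd_between", {
  cfg <- synthetic_config(n_participants = 200, seed = 5,
                          sd_between = c(steps = 1000, light = 30, mvpa = 10,
                                         sedentary = 50),
                          sd_within = c(steps = 50, light = 2, mvpa = 1,
                                        sedentary = 3),
                          weekday_effects = zero_weekday())
  gen <- generate_daily_records(cfg)
  dt <- data.table::as.data.table(gen$daily)
  # remove the population trend before averaging within participant
  dt[, mu := population_trend(cfg, "steps", date)]
  pm <- dt[, list(m = mean(steps - mu)), by = participant_id]
  expect_lt(abs(var(pm$m) - 1000^2) / 1000^2, 0.15)
})

test_that("dropout mode produces participants failing the valid-day filter", {
  cfg <- tiny_config(n = 10, seed = 3,
                     compliance = list(p_daily = 1),
                     dropout_after = as.Date("2020-05-01"))
  ws <- draw_wear_schedule(cfg)
  expect_true(all(ws$participants$true_valid_days < 250))
  expect_false(any(ws$participants$analyzed_true))
})
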