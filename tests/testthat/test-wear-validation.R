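mk_minutes <- function(bpm, start = "2020-01-01 08:00:00", id = "A") {
  data.frame(participant_id = rep(id, length(bpm)),
             timestamp = as.POSIXct(start, tz = "UTC") + 60 * (seq_along(bpm) - 1),
             bpm = bpm)
}

test_that("aphysiologic filtering keeps exactly the 50-200 bpm band", {
  rec <- mk_minutes(c(49, 50, 120, 200, 201))
  out <- clean_heart_rate(rec)
  expect_equal(out$bpm, c(50, 120, 200))
  expect_equal(attr(out, "n_aphysiologic"), 2)

  # empty input -> empty output
  expect_equal(nrow(clean_heart_rate(mk_minutes(numeric(0)))), 0)

  # brute-force count on uniform bpm draws
  set.seed(8)
  bpm <- sample(40:210, 1000, replace = TRUE)
  out <- clean_heart_rate(mk_minutes(bpm))
  expect_equal(nrow(out), sum(bpm >= 50 & bpm <= 200))
  # order preserved
  expect_equal(out$bpm, bpm[bpm >= 50 & bpm <= 200])

  # malformed records are rejected with a warning, not treated as aphysiologic
  recm <- mk_minutes(c(80, -5, 0, 90))
  expect_warning(outm <- clean_heart_rate(recm), "malformed")
  expect_equal(outm$bpm, c(80, 90))
  expect_equal(attr(outm, "n_malformed"), 2)
})

test_that("cleaning is idempotent", {
  set.seed(9)
  rec <- mk_minutes(sample(30:220, 300, replace = TRUE))
  once <- clean_heart_rate(rec)
  twice <- clean_heart_rate(once)
  expect_equal(strip_attrs(twice), strip_attrs(once))
})

test_that("wear minutes count distinct calendar minutes", {
  # 3 readings within the same minute -> 1 wear minute
  rec <- data.frame(participant_id = "A",
                    timestamp = as.POSIXct("2020-01-01 08:00:00", tz = "UTC") +
                      c(0, 10, 30),
                    bpm = c(80, 82, 84))
  w <- wear_minutes_per_day(rec)
  expect_equal(w$wear_minutes, 1)

  # readings at every minute of a day -> 1440
  full <- mk_minutes(rep(80, 1440), start = "2020-01-01 00:00:00")
  expect_equal(wear_minutes_per_day(full)$wear_minutes, 1440)

  # 700 distinct random minutes plus 50 duplicates -> 700
  set.seed(10)
  mins <- sample(0:1439, 700)
  ts <- as.POSIXct("2020-03-05", tz = "UTC") + 60 * c(mins, sample(mins, 50))
  rec <- data.frame(participant_id = "B", timestamp = ts, bpm = 90)
  expect_equal(wear_minutes_per_day(rec)$wear_minutes, 700)
})

test_that("sleep attribution clips at day boundaries and unions overlaps", {
  # overlapping episodes: union, not sum
  ep <- data.frame(participant_id = "A",
                   onset = as.POSIXct(c("2020-01-01 01:00:00",
                                        "2020-01-01 02:00:00"), tz = "UTC"),
                   offset = as.POSIXct(c("2020-01-01 03:00:00",
                                         "2020-01-01 04:00:00"), tz = "UTC"))
  sm <- sleep_minutes_per_day(ep)
  expect_equal(sm$sleep_minutes, 180)

  # inverted episode rejected with warning
  bad <- data.frame(participant_id = "A",
                    onset = as.POSIXct("2020-01-02 05:00:00", tz = "UTC"),
                    offset = as.POSIXct("2020-01-02 04:00:00", tz = "UTC"))
  expect_warning(out <- sleep_minutes_per_day(rbind(ep, bad)), "rejected")
  expect_equal(out$sleep_minutes, 180)

  # random episodes match the minute-grid marking oracle
  set.seed(11)
  n_ep <- 100
  onset <- as.POSIXct("2020-02-01", tz = "UTC") +
    runif(n_ep, 0, 5 * 86400)
  onset <- as.POSIXct(60 * floor(as.numeric(onset) / 60),
                      tz = "UTC", origin = "1970-01-01")
  dur <- 60 * sample(10:600, n_ep, replace = TRUE)
  ep <- data.frame(participant_id = sample(c("A", "B"), n_ep, TRUE),
                   onset = onset, offset = onset + dur)
  got <- sleep_minutes_per_day(ep)
  oracle <- minute_grid_oracle(
    data.frame(participant_id = character(0),
               timestamp = as.POSIXct(character(0), tz = "UTC"),
               bpm = numeric(0)), ep)
  oracle <- oracle[oracle$sleep_minutes > 0, ]
  got <- got[order(got$participant_id, got$date), ]
  oracle <- oracle[order(oracle$participant_id, oracle$date), ]
  expect_equal(got$sleep_minutes, oracle$sleep_minutes)
  expect_equal(got$date, oracle$date)
})

test_that("day assessment applies the day-wear arithmetic and 600-minute rule", {
  wear <- data.frame(participant_id = "A",
                     date = as.Date("2020-01-01") + 0:3,
                     wear_minutes = c(700, 650, 650, 300))
  sleep <- data.frame(participant_id = "A",
                      date = as.Date("2020-01-01") + 0:3,
                      sleep_minutes = c(90, 51, 50, 400))
  a <- assess_days(wear, sleep)
  expect_equal(a$day_wear_minutes, c(610, 599, 600, 0))
  expect_equal(a$is_valid_day, c(TRUE, FALSE, TRUE, FALSE))

  # missing sleep -> sleep 0; sleep-only date -> wear 0, invalid
  w2 <- data.frame(participant_id = "B", date = as.Date("2020-01-01"),
                   wear_minutes = 700)
  s2 <- data.frame(participant_id = "B", date = as.Date("2020-01-02"),
                   sleep_minutes = 400)
  a2 <- assess_days(w2, s2)
  expect_equal(a2$day_wear_minutes[a2$date == as.Date("2020-01-01")], 700)
  expect_equal(a2$wear_minutes[a2$date == as.Date("2020-01-02")], 0)
  expect_false(a2$is_valid_day[a2$date == as.Date("2020-01-02")])
})

test_that("participant selection applies the 250-valid-day cutoff", {
  mk_ass <- function(id, nvalid) {
    dates <- seq(as.Date("2019-11-01"), by = "day", length.out = 365)
    data.frame(participant_id = id, date = dates,
               wear_minutes = 1000, sleep_minutes = 0,
               day_wear_minutes = c(rep(700, nvalid), rep(100, 365 - nvalid)),
               is_valid_day = c(rep(TRUE, nvalid), rep(FALSE, 365 - nvalid)))
  }
  ass <- rbind(mk_ass("A", 250), mk_ass("B", 249), mk_ass("C", 365))
  sel <- select_participants(ass)
  expect_equal(sel$included, c(TRUE, FALSE, TRUE))
  expect_equal(sel$valid_days, c(250, 249, 365))

  # synthetic cohort: inclusion equals a direct recount
  cfg <- tiny_config(n = 12, seed = 17)
  ws <- draw_wear_schedule(cfg)
  ass2 <- schedule_to_assessments(ws$schedule)
  sel2 <- select_participants(ass2)
  recount <- tapply(ass2$is_valid_day, ass2$participant_id, sum)
  expect_equal(sel2$valid_days, as.vector(recount[sel2$participant_id]))
  expect_equal(sel2$participant_id[sel2$included],
               ws$participants$participant_id[ws$participants$analyzed_true])
})

test_that("full chain equals the minute-grid brute-force oracle", {
  cfg <- tiny_config(n = 4, seed = 23, hr_artifact_rate = 0.05)
  sim <- simulate_cohort(cfg, minute_level = TRUE)
  # restrict to a 6-day window to keep the oracle cheap
  win <- as.Date("2020-01-10") + 0:5
  mins <- sim$minutes[as.Date(sim$minutes$timestamp, tz = "UTC") %in% win, ]
  eps <- sim$sleep[as.Date(sim$sleep$onset, tz = "UTC") %in% win &
                     as.Date(sim$sleep$offset - 1, tz = "UTC") %in% win, ]
  got <- assess_days(wear_minutes_per_day(clean_heart_rate(mins)),
                     sleep_minutes_per_day(eps))
  oracle <- minute_grid_oracle(mins, eps)
  key <- function(d) paste(d$participant_id, d$date)
  oracle <- oracle[match(key(got), key(oracle)), ]
  expect_equal(got$wear_minutes, oracle$wear_minutes)
  expect_equal(got$sleep_minutes, oracle$sleep_minutes)
  expect_equal(got$day_wear_minutes, oracle$day_wear_minutes)
  expect_equal(got$is_valid_day, oracle$is_valid_day)
})

test_that("conservation and monotonicity of the filtering chain", {
  cfg <- tiny_config(n = 8, seed = 29)
  sim <- simulate_cohort(cfg, minute_level = TRUE)
  ass <- assess_days(wear_minutes_per_day(clean_heart_rate(sim$minutes)),
                     sleep_minutes_per_day(sim$sleep))
  expect_true(all(ass$wear_minutes >= ass$day_wear_minutes))
  expect_true(all(ass$day_wear_minutes >= 0))
  expect_true(all(ass$wear_minutes <= 1440))

  # stricter thresholds never enlarge the included set
  base <- validation_params()
  sel0 <- select_participants(ass, base)
  inc0 <- sel0$participant_id[sel0$included]
  for (p in list(validation_params(valid_day_threshold = 700),
                 validation_params(min_valid_days = 300))) {
    ass_p <- assess_days(wear_minutes_per_day(clean_heart_rate(sim$minutes, p)),
                         sleep_minutes_per_day(sim$sleep), p)
    sel_p <- select_participants(ass_p, p)
    expect_true(all(sel_p$participant_id[sel_p$included] %in% inc0))
  }
  # narrower heart-rate band likewise
  pnarrow <- validation_params(hr_lower = 60, hr_upper = 180)
  assn <- assess_days(wear_minutes_per_day(clean_heart_rate(sim$minutes, pnarrow)),
                      sleep_minutes_per_day(sim$sleep), pnarrow)
  seln <- select_participants(assn, pnarrow)
  expect_true(all(seln$participant_id[seln$included] %in% inc0))
})
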