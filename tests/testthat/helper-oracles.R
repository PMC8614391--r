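# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own optimised code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# minute-grid oracle: per participant-day boolean arrays of 1440 minutes
# marking valid-HR wear and sleep, reproducing the whole validation chain
minute_grid_oracle <- function(minutes, sleep, params = validation_params()) {
  keys <- unique(rbind(
    data.frame(participant_id = minutes$participant_id,
               date = as.Date(minutes$timestamp, tz = "UTC")),
    data.frame(participant_id = sleep$participant_id,
               date = as.Date(sleep$onset, tz = "UTC")),
    data.frame(participant_id = sleep$participant_id,
               date = as.Date(sleep$offset - 1, tz = "UTC"))
  ))
  keys <- keys[order(keys$participant_id, keys$date), ]
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    pid <- keys$participant_id[r]; d <- keys$date[r]
    day0 <- as.numeric(as.POSIXct(as.character(d), tz = "UTC"))
    worn <- rep(FALSE, 1440)
    sel <- minutes$participant_id == pid &
      minutes$timestamp >= day0 & minutes$timestamp < day0 + 86400 &
      minutes$bpm >= params$hr_lower & minutes$bpm <= params$hr_upper
    if (any(sel)) {
      mins <- floor((as.numeric(minutes$timestamp[sel]) - day0) / 60) + 1
      worn[unique(mins)] <- TRUE
    }
    slept <- rep(FALSE, 1440)
    ep <- sleep[sleep$participant_id == pid, , drop = FALSE]
    for (k in seq_len(nrow(ep))) {
      a <- as.numeric(ep$onset[k]); b <- as.numeric(ep$offset[k])
      if (b <= a) next
      for (mm in 0:1439) {
        ms <- day0 + 60 * mm
        if (ms < b && ms + 60 > a) slept[mm + 1] <- TRUE
      }
    }
    w <- sum(worn); s <- sum(slept)
    data.frame(participant_id = pid, date = d, wear_minutes = w,
               sleep_minutes = s,
               day_wear_minutes = max(0, w - s),
               is_valid_day = max(0, w - s) >= params$valid_day_threshold)
  })
  do.call(rbind, rows)
}

# exhaustive optimal partition: enumerate all admissible break vectors,
# computing each segment's RSS from first principles
enum_partition <- function(y, m, h) {
  n <- length(y)
  rss1 <- function(i, j) { s <- y[i:j]; sum((s - mean(s))^2) }
  if (m == 0) return(list(breaks = integer(0), rss = rss1(1, n)))
  combos <- utils::combn(n - 1, m)
  best <- Inf; best_b <- NULL
  for (c_i in seq_len(ncol(combos))) {
    b <- combos[, c_i]
    lens <- diff(c(0, b, n))
    if (any(lens < h)) next
    bounds <- c(0, b, n)
    tot <- 0
    for (s in seq_len(m + 1)) tot <- tot + rss1(bounds[s] + 1, bounds[s + 1])
    if (tot < best - 1e-12) { best <- tot; best_b <- b }
  }
  list(breaks = best_b, rss = best)
}

# small, fast synthetic config for unit tests
tiny_config <- function(n = 4, seed = 1, ...) {
  synthetic_config(n_participants = n, seed = seed, ...)
}

strip_attrs <- function(d) {
  attributes(d)[setdiff(names(attributes(d)),
                        c("names", "row.names", "class"))] <- NULL
  rownames(d) <- NULL
  d
}

zero_weekday <- function() {
  setNames(lapply(OUTCOMES, function(o) rep(0, 7)), OUTCOMES)
}
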