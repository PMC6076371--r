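# Shared fixture builders and independent oracles.

epoch <- function(s) as.POSIXct(s, origin = "1970-01-01", tz = "UTC")

make_events <- function(times_s, classes = "REGULAR", subject = "s1",
                        offset_s = 0L) {
  tibble::tibble(
    subject_id = subject,
    timestamp = epoch(times_s),
    utc_offset_s = as.integer(offset_s),
    event_class = rep_len(classes, length(times_s))
  )
}

make_accel <- function(times_s, x, y, z, subject = "s1", offset_s = 0L) {
  tibble::tibble(
    subject_id = subject,
    timestamp = epoch(times_s),
    utc_offset_s = as.integer(offset_s),
    x = x, y = y, z = z
  )
}

make_assessment <- function(assessed_s, scale = "HDRS17", score = 10L,
                            subject = "s1", offset_s = 0L) {
  tibble::tibble(
    subject_id = subject,
    assessed_at = epoch(assessed_s),
    utc_offset_s = as.integer(offset_s),
    scale = scale,
    score = as.integer(score)
  )
}

# Independent brute-force sessionizer: walks the sorted keypress times one by
# one, closing the open session whenever the gap reaches the threshold.
# Deliberately a different algorithm from the vectorized implementation.
brute_force_sessions <- function(times_s, gap = 5) {
  times_s <- sort(times_s)
  sessions <- list()
  cur <- c()
  for (t in times_s) {
    if (length(cur) == 0 || t - cur[length(cur)] < gap) {
      cur <- c(cur, t)
    } else {
      sessions[[length(sessions) + 1]] <- cur
      cur <- c(t)
    }
  }
  if (length(cur) > 0) sessions[[length(sessions) + 1]] <- cur
  sessions
}

random_keypress_times <- function(n, rate_fast = 1, p_break = 0.1) {
  # mixture of short within-session gaps and long inter-session breaks
  gaps <- ifelse(
    runif(n - 1) < p_break,
    5 + stats::rexp(n - 1, 1 / 30),
    stats::rexp(n - 1, rate_fast)
  )
  cumsum(c(stats::runif(1, 0, 10), gaps))
}

# small reduced-volume simulation config for fast tests; the cohort design
# (9 subjects x 8 weeks) and the outcome model are untouched
small_sim_config <- function(...) {
  simulation_config(
    sessions_per_day_mean = 4, keypresses_per_session_mean = 12,
    accel_sample_rate = 2, ...
  )
}
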