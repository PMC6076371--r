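# Sessionization and the seven weekly predictors. A typing session is a
# maximal run of keypresses in which every consecutive gap is < 5 s; a gap of
# exactly 5 s splits. AUTOCORRECT events are software events: they never
# start or extend a session, never enter interkey delays, and are excluded
# from the keypress denominator of both ratios.

keypresses_only <- function(events) {
  events[events$event_class %in% KEYPRESS_CLASSES, , drop = FALSE]
}

check_sorted <- function(events) {
  if (nrow(events) < 2) {
    return(invisible(TRUE))
  }
  t <- as.numeric(events$timestamp)
  same <- events$subject_id[-1] == events$subject_id[-nrow(events)]
  if (any(same & diff(t) < 0)) {
    stop("events must be sorted by timestamp within subject", call. = FALSE)
  }
  invisible(TRUE)
}

#' Assign keypresses to typing sessions
#'
#' Adds a per-subject `session_id` to the keypress events. A new session
#' starts at the first keypress and whenever the gap since the previous
#' keypress is at least `gap_threshold_s` (the threshold gap itself splits).
#' AUTOCORRECT events are dropped.
#'
#' @param events Event tibble sorted by timestamp within subject.
#' @param gap_threshold_s Session gap threshold in seconds (default 5).
#' @return Keypress tibble with an integer `session_id`, numbered per subject.
#' @export
assign_sessions <- function(events, gap_threshold_s = 5) {
  check_sorted(events)
  kp <- keypresses_only(events)
  if (nrow(kp) == 0) {
    kp$session_id <- integer()
    return(kp)
  }
  t <- as.numeric(kp$timestamp)
  new_subject <- c(TRUE, kp$subject_id[-1] != kp$subject_id[-nrow(kp)])
  new_session <- new_subject | c(TRUE, diff(t) >= gap_threshold_s)
  run <- cumsum(new_session)
  # renumber within subject
  first_run <- run[new_subject][cumsum(new_subject)]
  kp$session_id <- as.integer(run - first_run + 1L)
  kp
}

#' Segment a keypress stream into typing sessions
#'
#' @inheritParams assign_sessions
#' @return Tibble with one row per session: `subject_id`, `session_id`,
#'   `start`, `end`, `keypress_count`, `length_s` (last minus first keypress;
#'   0 for single-keypress sessions).
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   subject_id = "s1",
#'   timestamp = as.POSIXct(c(0, 1, 2, 8, 9), origin = "1970-01-01", tz = "UTC"),
#'   utc_offset_s = 0L, event_class = "REGULAR"
#' )
#' segment_sessions(ev)
segment_sessions <- function(events, gap_threshold_s = 5) {
  kp <- assign_sessions(events, gap_threshold_s)
  if (nrow(kp) == 0) {
    return(tibble::tibble(
      subject_id = character(), session_id = integer(),
      start = as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC"),
      keypress_count = integer(), length_s = numeric()
    ))
  }
  # sessions are contiguous runs in the sorted keypress stream, so the
  # summary reduces to first/last positions of each run (dplyr::summarise is
  # too slow here: this runs once per assessment window)
  new_run <- c(
    TRUE,
    kp$subject_id[-1] != kp$subject_id[-nrow(kp)] |
      kp$session_id[-1] != kp$session_id[-nrow(kp)]
  )
  first <- which(new_run)
  last <- c(first[-1] - 1L, nrow(kp))
  t <- as.numeric(kp$timestamp)
  tibble::tibble(
    subject_id = kp$subject_id[first],
    session_id = kp$session_id[first],
    start = kp$timestamp[first],
    end = kp$timestamp[last],
    keypress_count = last - first + 1L,
    length_s = t[last] - t[first]
  )
}

#' Average within-session interkey delay
#'
#' Mean of all consecutive within-session keypress gaps, pooled across the
#' sessions present in `events`. Gaps of `gap_threshold_s` or more never
#' contribute (they separate sessions).
#'
#' @inheritParams assign_sessions
#' @return Seconds, or `NA` when no within-session pair exists.
#' @export
average_interkey_delay <- function(events, gap_threshold_s = 5) {
  kp <- assign_sessions(events, gap_threshold_s)
  if (nrow(kp) < 2) {
    return(NA_real_)
  }
  t <- as.numeric(kp$timestamp)
  same <- kp$subject_id[-1] == kp$subject_id[-nrow(kp)] &
    kp$session_id[-1] == kp$session_id[-nrow(kp)]
  d <- diff(t)[same]
  if (length(d) == 0) NA_real_ else mean(d)
}

#' Backspace ratio and autocorrect rate
#'
#' Both use the keypress count (REGULAR + SPACE + BACKSPACE) as denominator;
#' autocorrect events appear only in the autocorrect numerator. An
#' autocorrect rate above 1 is possible in principle and is flagged with a
#' warning rather than clipped.
#'
#' @param events Event tibble (any window).
#' @return Named list with `backspace_ratio` and `autocorrect_rate`, both
#'   `NA` when the window holds no keypresses.
#' @export
keypress_ratios <- function(events) {
  n_kp <- sum(events$event_class %in% KEYPRESS_CLASSES)
  if (n_kp == 0) {
    return(list(backspace_ratio = NA_real_, autocorrect_rate = NA_real_))
  }
  rate <- sum(events$event_class == "AUTOCORRECT") / n_kp
  if (rate > 1) {
    warning("autocorrect events outnumber keypresses in window (rate ",
      signif(rate, 3), ")",
      call. = FALSE
    )
  }
  list(
    backspace_ratio = sum(events$event_class == "BACKSPACE") / n_kp,
    autocorrect_rate = rate
  )
}

#' Average accelerometer displacement magnitude
#'
#' Arithmetic mean of the per-sample Euclidean magnitudes
#' sqrt(x^2 + y^2 + z^2).
#'
#' @param samples Accelerometer tibble with `x`, `y`, `z` in m/s^2.
#' @return m/s^2, or `NA` when there are no samples.
#' @export
average_accel_displacement <- function(samples) {
  if (nrow(samples) == 0) {
    return(NA_real_)
  }
  mean(sqrt(samples$x^2 + samples$y^2 + samples$z^2))
}

#' Hourly keypress profile
#'
#' Counts keypresses by local clock hour (0-23), using the UTC offset
#' recorded on each event; no daylight-saving normalisation is applied.
#'
#' @param events Event tibble (AUTOCORRECT rows are ignored).
#' @return Integer vector of length 24; element h+1 is the count for hour h.
#' @export
hourly_profile <- function(events) {
  kp <- keypresses_only(events)
  if (nrow(kp) == 0) {
    return(integer(24))
  }
  h <- local_hour(kp$timestamp, kp$utc_offset_s)
  tabulate(h + 1L, nbins = 24L)
}

#' Circadian baseline similarity
#'
#' Cosine of the angle between a week's 24-hour keypress profile and the
#' subject's whole-study baseline profile. 1 means the week's diurnal pattern
#' is proportional to baseline; values near 0 mean activity fell in hours the
#' subject normally never types in.
#'
#' @param week,baseline Nonnegative numeric vectors of length 24.
#' @return Unitless value in \[0, 1\], or `NA` if either profile is all zero.
#' @export
circadian_similarity <- function(week, baseline) {
  stopifnot(length(week) == 24, length(baseline) == 24)
  if (any(week < 0) || any(baseline < 0)) {
    stop("hourly profiles must be nonnegative", call. = FALSE)
  }
  nw <- sqrt(sum(week^2))
  nb <- sqrt(sum(baseline^2))
  if (nw == 0 || nb == 0) {
    return(NA_real_)
  }
  sum(week * baseline) / (nw * nb)
}

# binary-search window (lo, hi] on a sorted numeric vector; returns indices
window_idx <- function(t_sorted, lo, hi) {
  if (length(t_sorted) == 0) {
    return(integer())
  }
  i1 <- findInterval(lo, t_sorted) # count of t <= lo, excluded
  i2 <- findInterval(hi, t_sorted) # count of t <= hi, included
  if (i2 <= i1) integer() else (i1 + 1L):i2
}

#' Build the weekly feature table
#'
#' One row per (subject, assessment), with the seven predictors computed on
#' the half-open week window `(assessed_at - 7 days, assessed_at]`. Rows with
#' no keypresses in the window keep `session_count = 0` and all
#' keypress-derived features missing; an assessment whose subject has no
#' stream at all yields a fully missing row and a message. The circadian
#' baseline is the subject's profile over the entire study period (all weeks
#' pooled, including the current one).
#'
#' @param events Event tibble from [read_event_log()] or [simulate_cohort()].
#' @param accel Accelerometer tibble.
#' @param assessments Assessment tibble.
#' @param gap_threshold_s Session gap threshold in seconds (default 5).
#' @return Tibble with assessment reference columns (`subject_id`, `scale`,
#'   `assessed_at`, `score`, `window_start`, `window_end`, `keypress_count`)
#'   and the columns of [mood_predictors()].
#' @export
build_feature_table <- function(events, accel, assessments, gap_threshold_s = 5) {
  check_sorted(events)
  ev_split <- split(seq_len(nrow(events)), events$subject_id)
  ac_split <- split(seq_len(nrow(accel)), accel$subject_id)
  baselines <- lapply(ev_split, function(idx) hourly_profile(events[idx, ]))
  ev_time <- as.numeric(events$timestamp)
  ac_time <- as.numeric(accel$timestamp)
  ac_mag <- sqrt(accel$x^2 + accel$y^2 + accel$z^2)

  n <- nrow(assessments)
  keypress_count <- integer(n)
  session_count <- integer(n)
  num <- function() rep(NA_real_, n)
  delay <- num()
  bsr <- num()
  acr <- num()
  circ <- num()
  disp <- num()
  slen <- num()

  for (i in seq_len(n)) {
    subj <- assessments$subject_id[i]
    hi <- as.numeric(assessments$assessed_at[i])
    lo <- hi - 7 * 86400
    eidx <- ev_split[[subj]]
    if (is.null(eidx)) {
      message(
        "build_feature_table: no stream for subject '", subj,
        "'; features missing"
      )
      keypress_count[i] <- NA_integer_
      session_count[i] <- NA_integer_
      next
    }
    widx <- eidx[window_idx(ev_time[eidx], lo, hi)]
    wev <- events[widx, , drop = FALSE]
    aidx <- ac_split[[subj]]
    wacidx <- aidx[window_idx(ac_time[aidx], lo, hi)]
    if (length(wacidx) > 0) disp[i] <- mean(ac_mag[wacidx])
    n_kp <- sum(wev$event_class %in% KEYPRESS_CLASSES)
    keypress_count[i] <- n_kp
    if (n_kp > 0) {
      sess <- segment_sessions(wev, gap_threshold_s)
      session_count[i] <- nrow(sess)
      slen[i] <- mean(sess$length_s)
      delay[i] <- average_interkey_delay(wev, gap_threshold_s)
      r <- keypress_ratios(wev)
      bsr[i] <- r$backspace_ratio
      acr[i] <- r$autocorrect_rate
      circ[i] <- circadian_similarity(hourly_profile(wev), baselines[[subj]])
    }
  }
  tibble::tibble(
    subject_id = assessments$subject_id,
    scale = assessments$scale,
    assessed_at = assessments$assessed_at,
    utc_offset_s = assessments$utc_offset_s,
    score = assessments$score,
    window_start = assessments$assessed_at - 7 * 86400,
    window_end = assessments$assessed_at,
    keypress_count = keypress_count,
    avg_interkey_delay = delay,
    backspace_ratio = bsr,
    autocorrect_rate = acr,
    circadian_similarity = circ,
    avg_accel_displacement = disp,
    avg_session_length = slen,
    session_count = session_count
  )
}
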