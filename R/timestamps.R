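# ISO-8601 timestamp handling. Instants are stored as POSIXct in UTC together
# with the subject-local UTC offset in seconds, so local clock-hour binning
# (circadian features) can honour the offset recorded on each record.

ISO_RE <- "^(\\d{4}-\\d{2}-\\d{2})[T ](\\d{2}:\\d{2}:\\d{2})(\\.\\d{1,6})?(Z|[+-]\\d{2}:?\\d{2})$"

offset_to_seconds <- function(off) {
  out <- integer(length(off))
  z <- off == "Z"
  rest <- sub(":", "", off[!z])
  sign <- ifelse(substr(rest, 1, 1) == "-", -1L, 1L)
  hh <- as.integer(substr(rest, 2, 3))
  mm <- as.integer(substr(rest, 4, 5))
  out[!z] <- sign * (hh * 3600L + mm * 60L)
  out
}

seconds_to_offset <- function(offset_s) {
  sign <- ifelse(offset_s < 0, "-", "+")
  a <- abs(as.integer(offset_s))
  sprintf("%s%02d:%02d", sign, a %/% 3600L, (a %% 3600L) %/% 60L)
}

# Parse ISO-8601 strings with explicit offset. Returns list(instant = POSIXct
# UTC, offset_s = integer, ok = logical); malformed entries have ok = FALSE.
parse_iso8601 <- function(x) {
  x <- as.character(x)
  ok <- !is.na(x) & grepl(ISO_RE, x)
  instant <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  offset_s <- rep(NA_integer_, length(x))
  if (any(ok)) {
    xs <- x[ok]
    date <- sub(ISO_RE, "\\1", xs)
    time <- sub(ISO_RE, "\\2", xs)
    frac <- sub(ISO_RE, "\\3", xs)
    off <- sub(ISO_RE, "\\4", xs)
    ms <- ifelse(frac == "", 0, round(as.numeric(frac) * 1000))
    base <- as.POSIXct(paste(date, time),
      tz = "UTC", format = "%Y-%m-%d %H:%M:%S"
    )
    offs <- offset_to_seconds(off)
    instant[ok] <- base + ms / 1000 - offs
    offset_s[ok] <- offs
  }
  list(instant = instant, offset_s = offset_s, ok = ok)
}

# Format an instant back to ISO-8601 in its local offset, millisecond
# precision, with explicit carry so 0.999999... never misprints.
format_iso8601 <- function(instant, offset_s) {
  tms <- round(as.numeric(instant) * 1000) + as.numeric(offset_s) * 1000
  secs <- floor(tms / 1000)
  ms <- as.integer(tms - secs * 1000)
  t <- as.POSIXct(secs, origin = "1970-01-01", tz = "UTC")
  sprintf(
    "%s.%03d%s", format(t, "%Y-%m-%dT%H:%M:%S"), ms,
    seconds_to_offset(offset_s)
  )
}

# Local clock hour (0-23) of an instant under a per-record UTC offset.
local_hour <- function(instant, offset_s) {
  s <- as.numeric(instant) + as.numeric(offset_s)
  as.integer(floor((s %% 86400) / 3600))
}

# ISO year-week label of the local calendar date, used for the one-assessment-
# per-subject-per-scale-per-week invariant.
local_iso_week <- function(instant, offset_s) {
  t <- as.POSIXct(as.numeric(instant) + as.numeric(offset_s),
    origin = "1970-01-01", tz = "UTC"
  )
  format(t, "%G-%V")
}
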