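# Readers and writers for the three on-disk stream formats. Both CSV (with
# header) and JSONL (one record per line) are supported; timestamps are
# ISO-8601 with an explicit UTC offset. Readers validate every record and
# report the 1-based file line of the first offending one.

#' @name stream-io
#' @title Read and write keystroke, accelerometer, and assessment streams
#'
#' @description
#' `read_event_log()` reads anonymized keyboard events (`subject_id`,
#' `timestamp`, `event_class` with classes `REGULAR`, `SPACE`, `BACKSPACE`,
#' `AUTOCORRECT`); `read_accel_log()` reads accelerometer displacement triples
#' (`subject_id`, `timestamp`, `x`, `y`, `z` in m/s^2); `read_assessments()`
#' reads weekly clinician ratings (`subject_id`, `assessed_at`, `scale` in
#' `HDRS17`/`YMRS`, integer `score`). The matching `write_*()` functions
#' round-trip the tibbles record for record.
#'
#' Output rows are always sorted by `(subject_id, timestamp)` (stable in file
#' order for millisecond ties, which are legal and flagged with a message),
#' so reader output is deterministic regardless of input record order.
#' Malformed records — unknown event class, non-numeric or non-finite
#' accelerometer components, out-of-range scores, or a second rating for the
#' same subject, scale, and local calendar week — raise an error naming the
#' offending line.
#'
#' @param path File path.
#' @param format `"csv"` or `"jsonl"`.
#' @param events,samples,assessments Tibbles as returned by the readers.
#' @return The readers return a tibble with parsed `timestamp` (POSIXct, UTC)
#'   and `utc_offset_s` columns alongside the record fields; writers return
#'   `path` invisibly.
NULL

read_raw_records <- function(path, format, required) {
  stopifnot(file.exists(path))
  format <- match.arg(format, c("csv", "jsonl"))
  if (file.size(path) == 0) {
    return(NULL)
  }
  if (format == "csv") {
    df <- data.table::fread(path,
      colClasses = "character", header = TRUE,
      sep = ",", na.strings = NULL, showProgress = FALSE, data.table = FALSE
    )
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(NULL)
    }
    df <- jsonlite::stream_in(textConnection(lines), verbose = FALSE)
    df[] <- lapply(df, as.character)
  }
  if (nrow(df) == 0) {
    return(NULL)
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(
      "malformed ", format, " file '", path, "': missing column(s) ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  df
}

# Line number of record i: CSV has a header line, JSONL does not.
record_line <- function(i, format) i + as.integer(format == "csv")

parse_timestamp_col <- function(df, col, path, format) {
  p <- parse_iso8601(df[[col]])
  if (!all(p$ok)) {
    bad <- which(!p$ok)[1]
    stop(
      "parse error in '", path, "' line ", record_line(bad, format),
      ": malformed timestamp '", df[[col]][bad], "'",
      call. = FALSE
    )
  }
  p
}

sort_stream <- function(tbl, time_col) {
  ord <- order(tbl$subject_id, as.numeric(tbl[[time_col]]), seq_len(nrow(tbl)),
    method = "radix"
  )
  tbl[ord, , drop = FALSE]
}

#' @rdname stream-io
#' @export
read_event_log <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  df <- read_raw_records(path, format, c("subject_id", "timestamp", "event_class"))
  if (is.null(df)) {
    return(empty_events())
  }
  p <- parse_timestamp_col(df, "timestamp", path, format)
  bad_class <- which(!(df$event_class %in% EVENT_CLASSES))
  if (length(bad_class) > 0) {
    stop(
      "parse error in '", path, "' line ", record_line(bad_class[1], format),
      ": unknown event_class '", df$event_class[bad_class[1]], "'",
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    subject_id = df$subject_id,
    timestamp = p$instant,
    utc_offset_s = p$offset_s,
    event_class = df$event_class
  )
  out <- sort_stream(out, "timestamp")
  dup <- duplicated(out[, c("subject_id", "timestamp")])
  if (any(dup)) {
    message(
      "read_event_log: ", sum(dup),
      " duplicate subject/timestamp record(s) kept in file order"
    )
  }
  out
}

empty_events <- function() {
  tibble::tibble(
    subject_id = character(),
    timestamp = as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC"),
    utc_offset_s = integer(),
    event_class = character()
  )
}

#' @rdname stream-io
#' @export
read_accel_log <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  df <- read_raw_records(path, format, c("subject_id", "timestamp", "x", "y", "z"))
  if (is.null(df)) {
    return(empty_accel())
  }
  p <- parse_timestamp_col(df, "timestamp", path, format)
  comps <- lapply(df[c("x", "y", "z")], function(v) {
    suppressWarnings(as.numeric(v))
  })
  bad <- which(!is.finite(comps$x) | !is.finite(comps$y) | !is.finite(comps$z))
  if (length(bad) > 0) {
    stop(
      "parse error in '", path, "' line ", record_line(bad[1], format),
      ": accelerometer components must be finite numbers",
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    subject_id = df$subject_id,
    timestamp = p$instant,
    utc_offset_s = p$offset_s,
    x = comps$x, y = comps$y, z = comps$z
  )
  sort_stream(out, "timestamp")
}

empty_accel <- function() {
  tibble::tibble(
    subject_id = character(),
    timestamp = as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC"),
    utc_offset_s = integer(),
    x = numeric(), y = numeric(), z = numeric()
  )
}

#' @rdname stream-io
#' @export
read_assessments <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  df <- read_raw_records(path, format, c("subject_id", "assessed_at", "scale", "score"))
  if (is.null(df)) {
    return(empty_assessments())
  }
  p <- parse_timestamp_col(df, "assessed_at", path, format)
  bad_scale <- which(!(df$scale %in% names(SCALE_RANGES)))
  if (length(bad_scale) > 0) {
    stop(
      "parse error in '", path, "' line ", record_line(bad_scale[1], format),
      ": unknown scale '", df$scale[bad_scale[1]], "'",
      call. = FALSE
    )
  }
  score <- suppressWarnings(as.numeric(df$score))
  for (i in seq_along(score)) {
    rng <- SCALE_RANGES[[df$scale[i]]]
    if (!is.finite(score[i]) || score[i] != round(score[i]) ||
      score[i] < rng[1] || score[i] > rng[2]) {
      stop(
        "validation error in '", path, "' line ", record_line(i, format),
        ": ", df$scale[i], " score '", df$score[i], "' outside [",
        rng[1], ", ", rng[2], "] or not an integer",
        call. = FALSE
      )
    }
  }
  out <- tibble::tibble(
    subject_id = df$subject_id,
    assessed_at = p$instant,
    utc_offset_s = p$offset_s,
    scale = df$scale,
    score = as.integer(score)
  )
  week <- local_iso_week(out$assessed_at, out$utc_offset_s)
  key <- paste(out$subject_id, out$scale, week, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(
      "validation error in '", path, "' line ", record_line(dup[1], format),
      ": more than one ", out$scale[dup[1]], " assessment for subject '",
      out$subject_id[dup[1]], "' in calendar week ", week[dup[1]],
      call. = FALSE
    )
  }
  sort_stream(out, "assessed_at")
}

empty_assessments <- function() {
  tibble::tibble(
    subject_id = character(),
    assessed_at = as.POSIXct(numeric(), origin = "1970-01-01", tz = "UTC"),
    utc_offset_s = integer(),
    scale = character(),
    score = integer()
  )
}

write_stream <- function(df, path, format) {
  format <- match.arg(format, c("csv", "jsonl"))
  if (format == "csv") {
    data.table::fwrite(df, path, quote = FALSE)
  } else {
    con <- file(path, open = "w")
    on.exit(close(con))
    if (nrow(df) > 0) {
      jsonlite::stream_out(df, con, verbose = FALSE, digits = NA)
    }
  }
  invisible(path)
}

#' @rdname stream-io
#' @export
write_event_log <- function(events, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  df <- data.frame(
    subject_id = events$subject_id,
    timestamp = format_iso8601(events$timestamp, events$utc_offset_s),
    event_class = events$event_class
  )
  write_stream(df, path, format)
}

#' @rdname stream-io
#' @export
write_accel_log <- function(samples, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  df <- data.frame(
    subject_id = samples$subject_id,
    timestamp = format_iso8601(samples$timestamp, samples$utc_offset_s),
    # %.17g guarantees doubles survive the text round trip exactly
    x = sprintf("%.17g", samples$x),
    y = sprintf("%.17g", samples$y),
    z = sprintf("%.17g", samples$z)
  )
  if (format == "jsonl") {
    df$x <- samples$x
    df$y <- samples$y
    df$z <- samples$z
  }
  write_stream(df, path, format)
}

#' @rdname stream-io
#' @export
write_assessments <- function(assessments, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  df <- data.frame(
    subject_id = assessments$subject_id,
    assessed_at = format_iso8601(assessments$assessed_at, assessments$utc_offset_s),
    scale = assessments$scale,
    score = assessments$score
  )
  write_stream(df, path, format)
}
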