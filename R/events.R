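#' Build an event stream from vectors
#'
#' An event stream is the package's central container: a tibble with one row
#' per contiguous period of a single activity class, as exported in event
#' format by thigh-worn monitor software. Columns are `subject_id`, `start`
#' (POSIXct, naive local time stored as UTC), `duration_s`, `activity`
#' (`"sedentary"`, `"standing"` or `"stride"`) and `steps`. Every detected
#' stride event carries exactly two steps; sedentary and standing events
#' carry zero.
#'
#' @param subject_id Subject identifier (recycled if length 1).
#' @param start Event start times: POSIXct, ISO 8601 strings, or numeric
#'   seconds since the epoch. A single value with several events builds a
#'   contiguous stream from that origin (each event starts where the
#'   previous one ends).
#' @param duration_s Event durations in seconds (strictly positive).
#' @param activity Activity class of each event.
#' @param steps Step count per event; defaults to 2 for stride events and 0
#'   otherwise, which is the only pattern [validate_events()] accepts.
#' @param validate Run [validate_events()] on the result (default `TRUE`).
#'
#' @return A tibble of events, sorted by start time.
#' @examples
#' event_stream("S1", "2023-01-02 08:00:00",
#'              duration_s = c(600, 60, 1, 1),
#'              activity = c("sedentary", "standing", "stride", "stride"))
#' @export
event_stream <- function(subject_id, start, duration_s, activity, steps = NULL,
                         validate = TRUE) {
  if (is.character(start)) {
    start <- as.POSIXct(start, tz = "UTC",
                        tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  }
  start <- as_seconds(start)
  activity <- as.character(activity)
  if (is.null(steps)) steps <- ifelse(activity == "stride", 2L, 0L)
  n <- max(length(start), length(duration_s), length(activity))
  if (length(start) == 1L && n > 1L) {
    start <- start + c(0, cumsum(as.numeric(duration_s)))[seq_len(n)]
  }
  start <- as_timestamp(start)
  out <- tibble::tibble(
    subject_id = rep_len(as.character(subject_id), n),
    start = start,
    duration_s = as.numeric(duration_s),
    activity = activity,
    steps = as.integer(steps)
  )
  if (validate) validate_events(out) else out
}

#' Validate event-stream integrity
#'
#' Enforces the event-stream invariants: known activity codes, strictly
#' positive durations, two steps per stride event (zero otherwise),
#' non-empty subject ids, and — per subject — events sorted by start time
#' and contiguous, i.e. each event starts where the previous one ends, up to
#' `gap_tolerance`. Real monitor exports carry rounding jitter at event
#' boundaries, hence the tolerance; gaps larger than the tolerance but at
#' most `1` second can optionally be bridged by extending the earlier event.
#'
#' @param stream Event tibble as produced by [event_stream()] or
#'   [read_events()].
#' @param gap_tolerance Maximum unremarked gap/overlap between consecutive
#'   events, seconds (default 0.001).
#' @param bridge_gaps If `TRUE`, gaps in `(gap_tolerance, 1]` seconds are
#'   closed by extending the earlier event's duration; each bridge is
#'   reported via `message()`. Larger gaps are always an error.
#' @param strict_steps Require exactly 2 steps on every stride event. Set to
#'   `FALSE` only for streams split at day boundaries, where a stride's
#'   steps stay with the half containing its midpoint.
#'
#' @return The validated (possibly bridged, sorted) stream, invisibly
#'   usable in pipelines.
#' @export
validate_events <- function(stream, gap_tolerance = 0.001, bridge_gaps = FALSE,
                            strict_steps = TRUE) {
  required <- c("subject_id", "start", "duration_s", "activity", "steps")
  missing <- setdiff(required, names(stream))
  if (length(missing)) {
    stop("event stream is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(stream) == 0L) return(stream)

  bad <- which(is.na(stream$subject_id) | !nzchar(stream$subject_id))
  if (length(bad)) {
    stop("empty subject_id at row(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!stream$activity %in% .ACTIVITIES)
  if (length(bad)) {
    stop(sprintf("unknown activity code %s at row(s): %s",
                 paste(unique(stream$activity[bad]), collapse = "/"),
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(stream$duration_s) | stream$duration_s <= 0)
  if (length(bad)) {
    stop("non-positive duration at row(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  is_stride <- stream$activity == "stride"
  bad <- which(!is_stride & stream$steps != 0L)
  if (length(bad)) {
    stop("non-stride event with steps > 0 at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (strict_steps) {
    bad <- which(is_stride & stream$steps != 2L)
  } else {
    bad <- which(is_stride & !stream$steps %in% c(0L, 2L))
  }
  if (length(bad)) {
    stop("stride event must carry exactly 2 steps; violated at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }

  stream <- dplyr::arrange(stream, .data$subject_id, .data$start)
  start_s <- as_seconds(stream$start)
  end_s <- start_s + stream$duration_s
  same_subject <- stream$subject_id[-1L] == stream$subject_id[-nrow(stream)]
  gap <- start_s[-1L] - end_s[-nrow(stream)]
  gap[!same_subject] <- 0

  overlap <- which(gap < -gap_tolerance)
  if (length(overlap)) {
    stop("overlapping events beyond tolerance at row(s): ",
         paste(head(overlap + 1L, 5), collapse = ", "), call. = FALSE)
  }
  open <- which(gap > gap_tolerance)
  if (length(open)) {
    bridgeable <- gap[open] <= 1
    if (bridge_gaps && all(bridgeable)) {
      stream$duration_s[open] <- stream$duration_s[open] + gap[open]
      message(sprintf("bridged %d gap(s) of up to %.3f s by extending earlier events",
                      length(open), max(gap[open])))
    } else {
      stop(sprintf("non-contiguous events (gap %.3f s > tolerance) before row(s): %s%s",
                   max(gap[open]), paste(head(open + 1L, 5), collapse = ", "),
                   if (!bridge_gaps) "; set bridge_gaps = TRUE to close gaps <= 1 s" else ""),
           call. = FALSE)
    }
  }
  stream
}

#' Read an event CSV file
#'
#' Reads the package's event CSV dialect: UTF-8, RFC 4180, columns
#' `subject_id,start_iso8601,duration_s,activity,steps` with ISO 8601
#' timestamps and activity codes `sedentary`/`standing`/`stride`. The file
#' is validated on read ([validate_events()]); malformed rows, unknown
#' activity codes, zero durations and contiguity violations are errors
#' naming the offending row.
#'
#' @inheritParams validate_events
#' @param path Path to a CSV file.
#' @return A validated event tibble (possibly several subjects).
#' @export
read_events <- function(path, gap_tolerance = 0.001, bridge_gaps = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    start_iso8601 = readr::col_character(),
    duration_s = readr::col_double(),
    activity = readr::col_character(),
    steps = readr::col_integer()
  ), progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs)) {
    stop(sprintf("parse error in %s at row(s): %s", path,
                 paste(head(unique(probs$row), 5), collapse = ", ")),
         call. = FALSE)
  }
  required <- c("subject_id", "start_iso8601", "duration_s", "activity", "steps")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  start <- as.POSIXct(df$start_iso8601, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  alt <- is.na(start) & !is.na(df$start_iso8601)
  start[alt] <- as.POSIXct(df$start_iso8601[alt], tz = "UTC",
                           format = "%Y-%m-%d %H:%M:%OS")
  bad <- which(is.na(start) & !is.na(df$start_iso8601))
  if (length(bad)) {
    stop(sprintf("unparseable start_iso8601 in %s at row(s): %s", path,
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(
    subject_id = df$subject_id,
    start = start,
    duration_s = df$duration_s,
    activity = df$activity,
    steps = df$steps
  )
  validate_events(out, gap_tolerance = gap_tolerance, bridge_gaps = bridge_gaps)
}

#' Write an event stream to CSV
#'
#' Writes the event CSV dialect documented in [read_events()]. Timestamps
#' are written with microsecond precision so that a write/read round trip
#' reproduces the stream well within the 1 ms contract.
#'
#' @param stream Event tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(stream, path) {
  out <- tibble::tibble(
    subject_id = stream$subject_id,
    start_iso8601 = strftime(stream$start, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC"),
    duration_s = stream$duration_s,
    activity = stream$activity,
    steps = stream$steps
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Split an event stream at calendar-day boundaries
#'
#' The day is the unit of validity and of the per-day maxima, so each event
#' is assigned to the calendar day containing its start; an event spanning
#' midnight is cut at the boundary into two events whose durations sum to
#' the original. A split stride keeps its two steps on the half containing
#' the stride's midpoint, so total steps are conserved exactly. Days are
#' naive local calendar days with the boundary at 00:00.
#'
#' @param stream Validated event tibble (one or more subjects).
#' @return The stream with events cut at midnight and a `date` column
#'   added; use `split(x, x$date)` or `dplyr::group_by(date)` for per-day
#'   work.
#' @export
split_into_days <- function(stream) {
  if (nrow(stream) == 0L) {
    stream$date <- as.Date(character())
    return(stream)
  }
  s <- as_seconds(stream$start)
  d <- stream$duration_s
  steps <- as.integer(stream$steps)
  keep <- list()
  # an event can span several midnights; peel one day per pass
  repeat {
    boundary <- (floor(s / 86400) + 1) * 86400
    spans <- s + d > boundary + 1e-9
    if (!any(spans)) break
    first_part <- stream[spans, , drop = FALSE]
    d1 <- boundary[spans] - s[spans]
    mid <- s[spans] + d[spans] / 2
    first_part$start <- as_timestamp(s[spans])
    first_part$duration_s <- d1
    first_part$steps <- ifelse(mid < boundary[spans], steps[spans], 0L)
    keep[[length(keep) + 1L]] <- first_part
    # remainder continues from midnight
    steps[spans] <- ifelse(mid < boundary[spans], 0L, steps[spans])
    d[spans] <- d[spans] - d1
    s[spans] <- boundary[spans]
  }
  stream$start <- as_timestamp(s)
  stream$duration_s <- d
  stream$steps <- as.integer(steps)
  out <- dplyr::bind_rows(c(keep, list(stream)))
  out <- dplyr::arrange(out, .data$subject_id, .data$start)
  out$date <- as.Date(floor(as_seconds(out$start) / 86400), origin = "1970-01-01")
  out
}
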