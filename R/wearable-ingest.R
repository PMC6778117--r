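#' Parse a Fitbit-style JSON sleep log
#'
#' Reads one volunteer's sleep log in the documented JSON dialect (an array of
#' session objects with keys \code{startTime}, \code{endTime},
#' \code{minutesAsleep}, \code{timeInBed} and \code{awakeningsCount}; times
#' are ISO-8601 local clock times at minute resolution) and returns one row
#' per tracker-recorded sleep bout.
#'
#' Sleep efficiency is always recomputed as
#' \code{100 * minutes_asleep / minutes_in_bed} so that the definition of SE
#' (fraction of sleep time over time in bed) is single-sourced; any
#' efficiency value present in the file is ignored. Records violating the
#' session invariants (non-positive duration, asleep minutes exceeding in-bed
#' minutes, in-bed minutes exceeding the session span) are skipped, counted
#' and reported via a warning; they are never silently dropped.
#'
#' @param json JSON text, or the path of a file containing it.
#' @param volunteer_id Identifier attached to every parsed session.
#' @return A data frame with columns \code{volunteer_id}, \code{start},
#'   \code{end} (POSIXct, minute resolution), \code{minutes_asleep},
#'   \code{minutes_in_bed}, \code{wake_count} and \code{efficiency_pct},
#'   sorted by start time. Skipped records are described in the
#'   \code{"skipped"} attribute (a data frame with the session index and
#'   reason). Zero sessions is a valid result.
#' @seealso [parse_day_log()], [write_sleep_log()]
#' @export
parse_sleep_log <- function(json, volunteer_id = "unknown") {
  raw <- .read_json_input(json, what = "sleep log")
  if (length(raw) == 0L) {
    return(.empty_sessions(volunteer_id))
  }
  req <- c("startTime", "endTime", "minutesAsleep", "timeInBed", "awakeningsCount")
  skipped <- list()
  rows <- list()
  for (i in seq_along(raw)) {
    rec <- raw[[i]]
    missing <- setdiff(req, names(rec))
    if (length(missing) > 0L) {
      stop("sleep log schema error: session ", i, " is missing required key '",
           missing[1L], "'")
    }
    start <- .parse_ts(rec$startTime)
    end <- .parse_ts(rec$endTime)
    asleep <- as.numeric(rec$minutesAsleep)
    inbed <- as.numeric(rec$timeInBed)
    wakes <- as.numeric(rec$awakeningsCount)
    span_min <- as.numeric(difftime(end, start, units = "mins"))
    reason <- NULL
    if (!(end > start)) {
      reason <- "end_not_after_start"
    } else if (asleep < 0 || wakes < 0 || inbed <= 0) {
      reason <- "negative_or_zero_minutes"
    } else if (asleep > inbed) {
      reason <- "asleep_exceeds_in_bed"
    } else if (inbed > span_min + 1) {
      reason <- "in_bed_exceeds_session_span"
    }
    if (!is.null(reason)) {
      skipped[[length(skipped) + 1L]] <- data.frame(index = i, reason = reason,
                                                    stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      volunteer_id = volunteer_id,
      start = start,
      end = end,
      minutes_asleep = asleep,
      minutes_in_bed = inbed,
      wake_count = wakes,
      efficiency_pct = 100 * asleep / inbed,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else .empty_sessions(volunteer_id)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  skips <- if (length(skipped) > 0L) do.call(rbind, skipped) else
    data.frame(index = integer(0), reason = character(0), stringsAsFactors = FALSE)
  attr(out, "skipped") <- skips
  if (nrow(skips) > 0L) {
    warning("parse_sleep_log: skipped ", nrow(skips), " invalid session record(s) for '",
            volunteer_id, "' (", paste(unique(skips$reason), collapse = ", "), ")")
  }
  out
}

.empty_sessions <- function(volunteer_id) {
  out <- data.frame(
    volunteer_id = character(0),
    start = as.POSIXct(character(0), tz = "UTC"),
    end = as.POSIXct(character(0), tz = "UTC"),
    minutes_asleep = numeric(0),
    minutes_in_bed = numeric(0),
    wake_count = numeric(0),
    efficiency_pct = numeric(0),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- data.frame(index = integer(0), reason = character(0),
                                     stringsAsFactors = FALSE)
  out
}

#' Parse a Fitbit-style JSON day log
#'
#' Reads one volunteer's per-day tracker coverage records (array of objects
#' with keys \code{date}, \code{hrCoverageHours}, \code{steps}). These carry
#' the inputs to the day-completeness quality control: hours of intraday
#' heart-rate coverage and the daily step total.
#'
#' @param json JSON text or a file path.
#' @param volunteer_id Identifier attached to every parsed day.
#' @return Data frame with columns \code{volunteer_id}, \code{date} (Date),
#'   \code{hr_coverage_hours}, \code{total_steps}, sorted by date.
#' @export
parse_day_log <- function(json, volunteer_id = "unknown") {
  raw <- .read_json_input(json, what = "day log")
  if (length(raw) == 0L) {
    return(data.frame(volunteer_id = character(0), date = as.Date(character(0)),
                      hr_coverage_hours = numeric(0), total_steps = numeric(0),
                      stringsAsFactors = FALSE))
  }
  req <- c("date", "hrCoverageHours", "steps")
  rows <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    rec <- raw[[i]]
    missing <- setdiff(req, names(rec))
    if (length(missing) > 0L) {
      stop("day log schema error: day ", i, " is missing required key '", missing[1L], "'")
    }
    hrs <- as.numeric(rec$hrCoverageHours)
    steps <- as.numeric(rec$steps)
    if (is.na(hrs) || hrs < 0 || hrs > 24) {
      stop("day log validation error: hrCoverageHours = ", rec$hrCoverageHours,
           " outside [0, 24] at day ", i)
    }
    if (is.na(steps) || steps < 0) {
      stop("day log validation error: negative steps at day ", i)
    }
    rows[[i]] <- data.frame(volunteer_id = volunteer_id, date = as.Date(rec$date),
                            hr_coverage_hours = hrs, total_steps = steps,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$date)) {
    dup <- out$date[duplicated(out$date)][1L]
    stop("day log schema error: duplicate date ", format(dup), " for volunteer '",
         volunteer_id, "'")
  }
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.read_json_input <- function(json, what = "input") {
  txt <- json
  if (length(json) == 1L && !grepl("[\\[{]", json) && file.exists(json)) {
    txt <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON in ", what, ": ", conditionMessage(e),
                             call. = FALSE)
  )
}

#' Serialize parsed records back to the JSON dialect
#'
#' Inverse of [parse_sleep_log()] / [parse_day_log()]; re-parsing the output
#' yields identical records (round-trip property).
#'
#' @param sessions Data frame as returned by [parse_sleep_log()].
#' @return JSON text.
#' @export
write_sleep_log <- function(sessions) {
  recs <- lapply(seq_len(nrow(sessions)), function(i) {
    list(
      startTime = .fmt_ts(sessions$start[i]),
      endTime = .fmt_ts(sessions$end[i]),
      minutesAsleep = sessions$minutes_asleep[i],
      timeInBed = sessions$minutes_in_bed[i],
      awakeningsCount = sessions$wake_count[i]
    )
  })
  as.character(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA))
}

#' @rdname write_sleep_log
#' @param days Data frame as returned by [parse_day_log()].
#' @export
write_day_log <- function(days) {
  recs <- lapply(seq_len(nrow(days)), function(i) {
    list(
      date = format(days$date[i]),
      hrCoverageHours = days$hr_coverage_hours[i],
      steps = days$total_steps[i]
    )
  })
  as.character(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA))
}

#' Read a directory of per-volunteer wearable logs
#'
#' Expects one file per volunteer per stream, named \code{<id>.sleep.json}
#' and \code{<id>.days.json}; the volunteer id is taken from the file name.
#'
#' @param dir Directory path.
#' @return List with elements \code{sessions} and \code{days}, each a data
#'   frame pooled over volunteers, plus \code{skipped} summarizing records
#'   rejected during parsing.
#' @export
read_wearable_dir <- function(dir) {
  sleep_files <- list.files(dir, pattern = "\\.sleep\\.json$", full.names = TRUE)
  day_files <- list.files(dir, pattern = "\\.days\\.json$", full.names = TRUE)
  parse_many <- function(files, suffix, fun) {
    out <- lapply(files, function(f) {
      id <- sub(suffix, "", basename(f))
      fun(f, volunteer_id = id)
    })
    out
  }
  sess <- parse_many(sleep_files, "\\.sleep\\.json$", parse_sleep_log)
  days <- parse_many(day_files, "\\.days\\.json$", parse_day_log)
  skipped <- do.call(rbind, c(
    lapply(sess, function(s) {
      sk <- attr(s, "skipped")
      if (nrow(sk) > 0L) cbind(volunteer_id = s$volunteer_id[1L], sk) else NULL
    }),
    list(NULL)))
  list(
    sessions = do.call(rbind, c(sess, list(.empty_sessions("x")[0, ]))),
    days = do.call(rbind, days),
    skipped = skipped
  )
}
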