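#' Assign sleep sessions to nights
#'
#' A session belongs to the night of calendar day D when it starts in the
#' half-open window \[20:00 of D, 08:00 of D+1). Sessions starting between
#' 08:00 and 20:00 are naps and remain unassigned (\code{night_of = NA});
#' they never contribute to nightly totals. The half-open convention means a
#' session starting exactly at 08:00 is excluded and no session can belong
#' to two nights.
#'
#' @param sessions Session data frame from [parse_sleep_log()].
#' @param window_start,window_end Night window bounds as \code{"HH:MM"}
#'   (defaults 20:00 and 08:00).
#' @return The input with a \code{night_of} Date column added; the number of
#'   unassigned (nap) sessions is in the \code{"n_unassigned"} attribute.
#' @export
assign_sessions_to_nights <- function(sessions, window_start = "20:00",
                                      window_end = "08:00") {
  ws <- .parse_clock(window_start)
  we <- .parse_clock(window_end)
  m <- .minute_of_day(sessions$start)
  d <- .date_of(sessions$start)
  night <- as.Date(rep(NA, nrow(sessions)))
  night[m >= ws] <- d[m >= ws]
  night[m < we] <- d[m < we] - 1L
  sessions$night_of <- night
  attr(sessions, "n_unassigned") <- sum(is.na(night))
  sessions
}

#' Per-night sleep summaries
#'
#' For each volunteer-night: total sleep time is the sum of assigned
#' sessions' asleep minutes, sleep efficiency is the unweighted mean of
#' their efficiencies, and awakenings is the sum of their wake counts.
#' Nights with no assigned session are simply absent.
#'
#' @param sessions Output of [assign_sessions_to_nights()]; unassigned
#'   sessions are ignored.
#' @return Data frame with columns \code{volunteer_id}, \code{night_of},
#'   \code{tst_minutes}, \code{se_pct}, \code{awakenings},
#'   \code{n_sessions}.
#' @export
summarize_nights <- function(sessions) {
  if (is.null(sessions$night_of)) {
    stop("sessions lack a night_of column; call assign_sessions_to_nights() first")
  }
  s <- sessions[!is.na(sessions$night_of), , drop = FALSE]
  if (nrow(s) == 0L) {
    return(data.frame(volunteer_id = character(0), night_of = as.Date(character(0)),
                      tst_minutes = numeric(0), se_pct = numeric(0),
                      awakenings = numeric(0), n_sessions = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(s$volunteer_id, s$night_of, drop = TRUE, lex.order = TRUE)
  parts <- split(s, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    data.frame(
      volunteer_id = p$volunteer_id[1L],
      night_of = p$night_of[1L],
      tst_minutes = sum(p$minutes_asleep),
      se_pct = mean(p$efficiency_pct),
      awakenings = sum(p$wake_count),
      n_sessions = nrow(p),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$volunteer_id, out$night_of), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Circular mean of clock times
#'
#' Averages clock times that may span midnight by mapping each time to
#' minutes elapsed since a window origin (default 20:00), taking the
#' arithmetic mean, and mapping back. With the default origin this is
#' well-defined for any set of times falling within one 24-h cycle starting
#' at 20:00 — exactly the situation of sleep onsets and wake times.
#'
#' @param times \code{"HH:MM"} character vector or POSIXct vector.
#' @param window_origin Origin clock time, \code{"HH:MM"}.
#' @return The mean as \code{"HH:MM"} (rounded to the minute); the exact
#'   fractional minute-of-day is in the \code{"minutes_of_day"} attribute.
#' @examples
#' circular_clock_mean(c("23:00", "01:00"))  # "00:00"
#' @export
circular_clock_mean <- function(times, window_origin = "20:00") {
  if (length(times) == 0L) stop("no times to average")
  m <- .parse_clock(times)
  o <- .parse_clock(window_origin)
  offsets <- (m - o) %% 1440
  res <- (o + mean(offsets)) %% 1440
  out <- .fmt_clock(res)
  attr(out, "minutes_of_day") <- res
  out
}

#' Per-volunteer sleep summary
#'
#' Averages one volunteer's nightly summaries: TST in hours is the mean of
#' nightly sleep-minute sums divided by 60, SE is the mean of nightly mean
#' efficiencies, and awakenings is the mean of nightly wake-count sums.
#' Sleep hour is the circular mean start time of window-assigned sessions of
#' duration at least \code{min_session_minutes} (default 3 h); wake hour is
#' the circular mean end time of those same sessions. Duration is measured
#' on in-bed minutes by default (a tracker session is a bed interval);
#' set \code{duration_basis = "asleep"} to use asleep minutes instead.
#'
#' @param sessions One volunteer's sessions with \code{night_of} assigned.
#' @param nights Optional precomputed [summarize_nights()] output for the
#'   volunteer (recomputed when \code{NULL}). Nights already filtered by QC
#'   gating should be passed here.
#' @param min_session_minutes Duration threshold for the sleep/wake-hour
#'   average, in minutes (default 180).
#' @param duration_basis \code{"in_bed"} (default) or \code{"asleep"}.
#' @return One-row data frame: \code{volunteer_id}, \code{n_nights},
#'   \code{tst_hours}, \code{se_pct}, \code{awakenings}, \code{sleep_hour},
#'   \code{wake_hour} (HH:MM, \code{NA} when no session passes the duration
#'   filter — flagged via the \code{clock_times_missing} column).
#' @export
summarize_volunteer <- function(sessions, nights = NULL,
                                min_session_minutes = 180,
                                duration_basis = c("in_bed", "asleep")) {
  duration_basis <- match.arg(duration_basis)
  if (nrow(sessions) == 0L) stop("summarize_volunteer: no sessions")
  id <- sessions$volunteer_id[1L]
  if (is.null(nights)) nights <- summarize_nights(sessions)
  nights <- nights[nights$volunteer_id == id, , drop = FALSE]
  if (nrow(nights) == 0L) stop("summarize_volunteer: no nights for volunteer '", id, "'")
  dur <- if (duration_basis == "in_bed") sessions$minutes_in_bed else sessions$minutes_asleep
  eligible <- !is.na(sessions$night_of) & dur >= min_session_minutes &
    sessions$night_of %in% nights$night_of
  if (any(eligible)) {
    sleep_hour <- as.character(circular_clock_mean(sessions$start[eligible]))
    wake_hour <- as.character(circular_clock_mean(sessions$end[eligible]))
    missing_clock <- FALSE
  } else {
    sleep_hour <- NA_character_
    wake_hour <- NA_character_
    missing_clock <- TRUE
  }
  data.frame(
    volunteer_id = id,
    n_nights = nrow(nights),
    tst_hours = mean(nights$tst_minutes) / 60,
    se_pct = mean(nights$se_pct),
    awakenings = mean(nights$awakenings),
    sleep_hour = sleep_hour,
    wake_hour = wake_hour,
    clock_times_missing = missing_clock,
    stringsAsFactors = FALSE
  )
}

#' Derive cohort sleep summaries from sessions and day logs
#'
#' The full derivation pipeline: assigns sessions to nights, gates each
#' night on completeness of its start day (a night is retained iff its
#' \code{night_of} date is data-complete for that volunteer), applies the
#' volunteer inclusion rule, and summarizes per volunteer.
#'
#' @param sessions Pooled session data frame.
#' @param days Pooled day data frame, or \code{NULL} to skip completeness
#'   gating (all nights retained, all volunteers included).
#' @param min_hours,min_complete_days QC thresholds, see [build_qc_report()].
#' @param window_start,window_end Night window, see
#'   [assign_sessions_to_nights()].
#' @param min_session_minutes,duration_basis See [summarize_volunteer()].
#' @return Data frame with one row per included volunteer (columns of
#'   [summarize_volunteer()]); the per-volunteer QC table is attached as the
#'   \code{"qc"} attribute and nightly summaries as \code{"nights"}.
#' @export
derive_sleep_summary <- function(sessions, days = NULL,
                                 min_hours = 20, min_complete_days = 3,
                                 window_start = "20:00", window_end = "08:00",
                                 min_session_minutes = 180,
                                 duration_basis = "in_bed") {
  sessions <- assign_sessions_to_nights(sessions, window_start, window_end)
  nights <- summarize_nights(sessions)
  qc <- NULL
  if (!is.null(days)) {
    qc <- qc_cohort(days, min_hours = min_hours, min_complete_days = min_complete_days)
    complete <- days[assess_day(days, min_hours = min_hours), c("volunteer_id", "date")]
    keep <- paste(nights$volunteer_id, nights$night_of) %in%
      paste(complete$volunteer_id, complete$date)
    nights <- nights[keep, , drop = FALSE]
    included <- qc$volunteer_id[qc$included]
    nights <- nights[nights$volunteer_id %in% included, , drop = FALSE]
    sessions <- sessions[sessions$volunteer_id %in% included, , drop = FALSE]
  }
  ids <- unique(nights$volunteer_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    summarize_volunteer(sessions[sessions$volunteer_id == id, , drop = FALSE],
                        nights = nights,
                        min_session_minutes = min_session_minutes,
                        duration_basis = duration_basis)
  }))
  if (is.null(out)) {
    out <- data.frame(volunteer_id = character(0), n_nights = integer(0),
                      tst_hours = numeric(0), se_pct = numeric(0),
                      awakenings = numeric(0), sleep_hour = character(0),
                      wake_hour = character(0), clock_times_missing = logical(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$volunteer_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc") <- qc
  attr(out, "nights") <- nights
  out
}
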