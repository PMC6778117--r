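# PSQI scoring. Component definitions follow the standard 19-item
# self-rated instrument: seven components, each 0-3, summing to a 0-21
# global score. Band edges for the sleep-duration and habitual-efficiency
# components are centralized here so boundary conventions are configurable
# in one place.

#' PSQI band edges
#'
#' The banding tables used by the duration (component 3) and habitual sleep
#' efficiency (component 4) scores. Duration: > 7 h scores 0, (6, 7\] scores
#' 1, \[5, 6\] scores 2, < 5 h scores 3. Efficiency: > 85\% scores 0,
#' \[75, 85\] scores 1, \[65, 75) scores 2, < 65\% scores 3.
#'
#' @return Named list with \code{duration_hours} and \code{efficiency_pct}
#'   threshold vectors.
#' @export
psqi_bands <- function() {
  list(duration_hours = c(score0_above = 7, score1_above = 6, score2_at_least = 5),
       efficiency_pct = c(score0_above = 85, score1_at_least = 75, score2_at_least = 65))
}

#' PSQI component 3: sleep duration
#'
#' Scores self-reported habitual sleep hours into the instrument's duration
#' bands (see [psqi_bands()]).
#'
#' @param sleep_hours Non-negative numeric vector of self-reported hours of
#'   sleep per night.
#' @param bands Duration thresholds (override for sensitivity analyses).
#' @return Integer scores in 0..3.
#' @export
score_component3 <- function(sleep_hours, bands = psqi_bands()$duration_hours) {
  if (any(is.na(sleep_hours))) stop("missing sleep_hours")
  if (any(sleep_hours < 0)) stop("sleep_hours must be non-negative")
  ifelse(sleep_hours > bands[["score0_above"]], 0L,
         ifelse(sleep_hours > bands[["score1_above"]], 1L,
                ifelse(sleep_hours >= bands[["score2_at_least"]], 2L, 3L)))
}

#' PSQI component 4: habitual sleep efficiency
#'
#' Habitual SE is self-reported sleep hours over self-reported time in bed
#' (rise time minus bed time, wrapping midnight), as a percentage, banded
#' per [psqi_bands()].
#'
#' @param sleep_hours Self-reported hours slept per night.
#' @param bed_time,rise_time \code{"HH:MM"} clock times.
#' @param bands Efficiency thresholds.
#' @return Data frame with \code{habitual_se_pct} and \code{score}.
#' @export
score_component4 <- function(sleep_hours, bed_time, rise_time,
                             bands = psqi_bands()$efficiency_pct) {
  if (any(is.na(sleep_hours)) || any(is.na(bed_time)) || any(is.na(rise_time))) {
    stop("missing sleep_hours, bed_time or rise_time")
  }
  tib_min <- (.parse_clock(rise_time) - .parse_clock(bed_time)) %% 1440
  if (any(tib_min == 0)) stop("time in bed is zero (bed_time equals rise_time)")
  se <- 100 * sleep_hours / (tib_min / 60)
  score <- ifelse(se > bands[["score0_above"]], 0L,
                  ifelse(se >= bands[["score1_at_least"]], 1L,
                         ifelse(se >= bands[["score2_at_least"]], 2L, 3L)))
  data.frame(habitual_se_pct = se, score = score)
}

#' PSQI question 5b: nocturnal awakenings frequency
#'
#' The raw frequency code (0: not during the past month, 1: less than once a
#' week, 2: once or twice a week, 3: three or more times a week) is itself
#' the score.
#'
#' @param frequency_code Integer codes in \{0, 1, 2, 3\}.
#' @return The validated codes as integers.
#' @export
score_question5b <- function(frequency_code) {
  .check_code(frequency_code, "question 5b")
}

.check_code <- function(code, label) {
  if (any(is.na(code))) stop("missing response for ", label)
  if (any(code != as.integer(code)) || any(code < 0 | code > 3)) {
    stop("response code out of range {0,1,2,3} for ", label)
  }
  as.integer(code)
}

# 0 -> 0, 1-2 -> 1, 3-4 -> 2, 5-6 -> 3 (components 2 and 7)
.band_sum_0_6 <- function(x) ifelse(x == 0, 0L, ifelse(x <= 2, 1L, ifelse(x <= 4, 2L, 3L)))

#' Score PSQI questionnaires
#'
#' Computes the seven component scores and the global score for a table of
#' responses, one row per volunteer. Expected columns: \code{volunteer_id},
#' \code{bed_time}, \code{rise_time} (HH:MM), \code{sleep_latency_minutes},
#' \code{sleep_hours}, the disturbance items \code{q5a}..\code{q5j}
#' (frequency codes 0-3), \code{q6_quality}, \code{q7_medication},
#' \code{q8_drowsy}, \code{q9_enthusiasm} (ordinal 0-3). Bed-partner items
#' are not part of the scored instrument. Missing items are an error (no
#' imputation), naming the offending column.
#'
#' Components: 1 subjective quality (item 6); 2 latency (banded latency
#' minutes plus item 5a, re-banded); 3 duration ([score_component3()]);
#' 4 habitual efficiency ([score_component4()]); 5 disturbances (sum of
#' 5b..5j banded 0 / 1-9 / 10-18 / 19-27); 6 medication use (item 7);
#' 7 daytime dysfunction (items 8 + 9, re-banded). Global = sum, 0-21.
#'
#' @param responses Data frame of raw responses.
#' @return Data frame with \code{volunteer_id}, \code{component1..7},
#'   \code{global}, \code{habitual_se_pct}.
#' @export
score_psqi <- function(responses) {
  need <- c("volunteer_id", "bed_time", "rise_time", "sleep_latency_minutes",
            "sleep_hours", paste0("q5", letters[1:10]),
            "q6_quality", "q7_medication", "q8_drowsy", "q9_enthusiasm")
  miss <- setdiff(need, names(responses))
  if (length(miss) > 0L) stop("PSQI responses missing column '", miss[1L], "'")
  for (col in setdiff(need, "volunteer_id")) {
    if (any(is.na(responses[[col]]))) {
      bad <- responses$volunteer_id[is.na(responses[[col]])][1L]
      stop("missing PSQI item '", col, "' for volunteer '", bad, "'")
    }
  }
  c1 <- .check_code(responses$q6_quality, "q6_quality")
  lat <- responses$sleep_latency_minutes
  if (any(lat < 0)) stop("sleep_latency_minutes must be non-negative")
  lat_score <- ifelse(lat <= 15, 0L, ifelse(lat <= 30, 1L, ifelse(lat <= 60, 2L, 3L)))
  c2 <- .band_sum_0_6(lat_score + .check_code(responses$q5a, "q5a"))
  c3 <- score_component3(responses$sleep_hours)
  c4df <- score_component4(responses$sleep_hours, responses$bed_time, responses$rise_time)
  dist_items <- paste0("q5", letters[2:10])
  dist_sum <- Reduce(`+`, lapply(dist_items, function(cn) .check_code(responses[[cn]], cn)))
  c5 <- ifelse(dist_sum == 0, 0L, ifelse(dist_sum <= 9, 1L,
                                         ifelse(dist_sum <= 18, 2L, 3L)))
  c6 <- .check_code(responses$q7_medication, "q7_medication")
  c7 <- .band_sum_0_6(.check_code(responses$q8_drowsy, "q8_drowsy") +
                        .check_code(responses$q9_enthusiasm, "q9_enthusiasm"))
  data.frame(
    volunteer_id = responses$volunteer_id,
    component1 = c1, component2 = c2, component3 = c3, component4 = c4df$score,
    component5 = c5, component6 = c6, component7 = c7,
    global = c1 + c2 + c3 + c4df$score + c5 + c6 + c7,
    habitual_se_pct = c4df$habitual_se_pct,
    stringsAsFactors = FALSE
  )
}

#' Score a single PSQI response
#'
#' Convenience wrapper around [score_psqi()] for one response supplied as a
#' named list.
#'
#' @param response Named list with the fields documented in [score_psqi()].
#' @return Named list of component scores, global score and habitual SE.
#' @export
score_global <- function(response) {
  df <- as.data.frame(response, stringsAsFactors = FALSE)
  if (is.null(df$volunteer_id)) df$volunteer_id <- "r1"
  scores <- score_psqi(df)
  as.list(scores[1L, setdiff(names(scores), "volunteer_id")])
}
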