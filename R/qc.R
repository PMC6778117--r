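#' Day-completeness predicate
#'
#' A tracker day is data-complete when it has at least \code{min_hours} hours
#' of intraday heart-rate coverage and a nonzero step count. Days failing
#' either condition carry too little wear time to trust the night's sleep
#' record.
#'
#' @param days Data frame with columns \code{hr_coverage_hours} and
#'   \code{total_steps} (as produced by [parse_day_log()]).
#' @param min_hours Minimum heart-rate coverage, in hours (default 20).
#' @return Logical vector, one element per day.
#' @export
assess_day <- function(days, min_hours = 20) {
  stopifnot(all(c("hr_coverage_hours", "total_steps") %in% names(days)))
  days$hr_coverage_hours >= min_hours & days$total_steps > 0
}

#' Volunteer inclusion report
#'
#' Counts a single volunteer's data-complete days and applies the cohort
#' inclusion rule: a volunteer is included when at least
#' \code{min_complete_days} days are complete.
#'
#' @param days Data frame of one volunteer's tracker days; an empty frame
#'   yields an excluded report with zero totals.
#' @param min_hours Passed to [assess_day()].
#' @param min_complete_days Minimum number of complete days (default 3).
#' @return One-row data frame: \code{volunteer_id}, \code{n_days_total},
#'   \code{n_days_complete}, \code{included}, \code{exclusion_reason}
#'   (\code{"none"} or \code{"too_few_complete_days"}).
#' @export
build_qc_report <- function(days, min_hours = 20, min_complete_days = 3) {
  if (nrow(days) > 0L && length(unique(days$volunteer_id)) > 1L) {
    stop("build_qc_report expects days from a single volunteer; got ",
         length(unique(days$volunteer_id)))
  }
  id <- if (nrow(days) > 0L) days$volunteer_id[1L] else NA_character_
  complete <- if (nrow(days) > 0L) assess_day(days, min_hours = min_hours) else logical(0)
  n_complete <- sum(complete)
  included <- n_complete >= min_complete_days
  data.frame(
    volunteer_id = id,
    n_days_total = nrow(days),
    n_days_complete = n_complete,
    included = included,
    exclusion_reason = if (included) "none" else "too_few_complete_days",
    stringsAsFactors = FALSE
  )
}

#' Cohort-level quality control
#'
#' Applies [build_qc_report()] per volunteer over a pooled day table.
#'
#' @inheritParams build_qc_report
#' @param days Data frame of tracker days for any number of volunteers.
#' @return Data frame with one QC row per volunteer, ordered by id.
#' @export
qc_cohort <- function(days, min_hours = 20, min_complete_days = 3) {
  parts <- split(days, days$volunteer_id)
  out <- do.call(rbind, lapply(parts, build_qc_report,
                               min_hours = min_hours,
                               min_complete_days = min_complete_days))
  out <- out[order(out$volunteer_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Optional extreme-activity outlier filter
#'
#' Flags volunteers whose mean daily step count falls outside the given
#' percentile band. Off by default in the pipeline: what counts as an
#' "extreme" activity outlier is a study-level choice, so the thresholds are
#' explicit arguments rather than built-in constants.
#'
#' @param mean_steps Named (by volunteer id) or plain numeric vector of mean
#'   daily steps.
#' @param lower,upper Percentiles in \[0, 1\] delimiting the retained band
#'   (e.g. 0.005 and 0.995); \code{NULL} disables that side.
#' @return Logical vector, \code{TRUE} for flagged (outlying) volunteers.
#' @export
flag_step_outliers <- function(mean_steps, lower = NULL, upper = NULL) {
  flag <- rep(FALSE, length(mean_steps))
  if (!is.null(lower)) {
    flag <- flag | mean_steps < stats::quantile(mean_steps, lower, na.rm = TRUE)
  }
  if (!is.null(upper)) {
    flag <- flag | mean_steps > stats::quantile(mean_steps, upper, na.rm = TRUE)
  }
  names(flag) <- names(mean_steps)
  flag
}
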