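# Internal clock/time helpers. All timestamps in this package are naive local
# clock times at minute resolution; no timezone arithmetic is performed (a
# single-timezone study design), so POSIXct values are pinned to UTC purely
# as a storage convention.

.TS_FORMATS <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M")

.parse_ts <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in .TS_FORMATS) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], format = fmt, tz = "UTC")
  }
  if (anyNA(out) && !anyNA(x)) {
    bad <- x[is.na(out)][1L]
    stop("unparseable timestamp: '", bad, "' (expected ISO-8601, e.g. 2016-01-01T23:10)")
  }
  out
}

.fmt_ts <- function(x) format(x, "%Y-%m-%dT%H:%M", tz = "UTC")

# "HH:MM" -> minutes after midnight
.parse_clock <- function(x) {
  if (inherits(x, "POSIXct")) {
    lt <- as.POSIXlt(x, tz = "UTC")
    return(lt$hour * 60 + lt$min)
  }
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("unparseable clock time: '", x[bad][1L], "' (expected HH:MM)")
  h <- vapply(m, function(g) as.integer(g[2L]), 1L)
  mi <- vapply(m, function(g) as.integer(g[3L]), 1L)
  if (any(h > 23 | mi > 59)) stop("clock time out of range: '", x[h > 23 | mi > 59][1L], "'")
  h * 60 + mi
}

# minutes after midnight -> "HH:MM" (rounded to the nearest minute)
.fmt_clock <- function(minutes) {
  m <- round(minutes) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

.minute_of_day <- function(ts) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  lt$hour * 60 + lt$min
}

.date_of <- function(ts) as.Date(ts, tz = "UTC")

# deterministic per-unit substream seed so volunteer i's draws do not depend
# on how many volunteers the cohort has
.substream_seed <- function(seed, index, stream = 0L) {
  as.integer((as.numeric(seed) * 1009 + index * 9973 + stream * 104729) %% 2147483629) + 1L
}
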