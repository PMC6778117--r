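# Fixture builders shared across test files. All fixtures are constructed in
# code; no data files are read.

session_json <- function(...) {
  recs <- list(...)
  as.character(jsonlite::toJSON(recs, auto_unbox = TRUE))
}

sess_rec <- function(start, end, asleep, inbed, wakes = 0) {
  list(startTime = start, endTime = end, minutesAsleep = asleep,
       timeInBed = inbed, awakeningsCount = wakes)
}

day_json <- function(...) {
  as.character(jsonlite::toJSON(list(...), auto_unbox = TRUE))
}

day_rec <- function(date, hr, steps) {
  list(date = date, hrCoverageHours = hr, steps = steps)
}

days_df <- function(hr, steps, id = "v1") {
  data.frame(volunteer_id = id,
             date = as.Date("2016-01-01") + seq_along(hr) - 1,
             hr_coverage_hours = hr, total_steps = steps,
             stringsAsFactors = FALSE)
}

sessions_df <- function(starts, asleep, inbed = NULL, wakes = 0, id = "v1") {
  if (is.null(inbed)) inbed <- asleep
  start <- as.POSIXct(starts, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  data.frame(volunteer_id = id, start = start, end = start + inbed * 60,
             minutes_asleep = asleep, minutes_in_bed = inbed,
             wake_count = rep_len(wakes, length(starts)),
             efficiency_pct = 100 * asleep / inbed,
             stringsAsFactors = FALSE)
}

# a complete PSQI response row; override fields as needed
psqi_row <- function(..., id = "v1") {
  base <- list(volunteer_id = id, bed_time = "23:00", rise_time = "07:00",
               sleep_latency_minutes = 10, sleep_hours = 7.5,
               q5a = 0, q5b = 0, q5c = 0, q5d = 0, q5e = 0, q5f = 0,
               q5g = 0, q5h = 0, q5i = 0, q5j = 0,
               q6_quality = 0, q7_medication = 0, q8_drowsy = 0,
               q9_enthusiasm = 0)
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(base, stringsAsFactors = FALSE)
}

# manual two-plate (T and S) qPCR well table with an ideal doubling curve
ideal_plate <- function(sample_concs, assay, plate_id, ctrl_conc = 35,
                        batch = "b1", shift = 1, intercept = 30) {
  slope <- -1 / log10(2)
  std_concs <- c(109.0, 36.3, 12.1, 4.0, 1.3)
  to_cq <- function(conc) slope * log10(conc) + intercept
  std <- data.frame(plate_id = plate_id, assay = assay,
                    sample_id = paste0("std", rep(seq_along(std_concs), each = 3)),
                    role = "standard", conc = rep(std_concs, each = 3),
                    batch = batch, stringsAsFactors = FALSE)
  std$cq <- to_cq(std$conc)
  ctrl <- data.frame(plate_id = plate_id, assay = assay, sample_id = "control",
                     role = "control", conc = NA_real_, batch = batch,
                     stringsAsFactors = FALSE)[rep(1, 3), ]
  ctrl$cq <- to_cq(rep(ctrl_conc * shift, 3))
  smp <- data.frame(plate_id = plate_id, assay = assay,
                    sample_id = rep(names(sample_concs), each = 3),
                    role = "sample", conc = NA_real_, batch = batch,
                    stringsAsFactors = FALSE)
  smp$cq <- to_cq(rep(sample_concs * shift, each = 3))
  rbind(std, ctrl, smp)
}
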