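test_that("sessions are assigned to nights by a half-open 20:00-08:00 start window", {
  s <- sessions_df(c("2016-01-01T23:30",  # evening -> its own date
                     "2016-01-02T02:15",  # after midnight -> previous date
                     "2016-01-01T14:00",  # afternoon nap -> unassigned
                     "2016-01-02T08:00",  # boundary: exactly 08:00 excluded
                     "2016-01-02T20:00"), # boundary: exactly 20:00 included
                   asleep = c(400, 350, 60, 300, 380))
  a <- assign_sessions_to_nights(s)
  expect_equal(a$night_of,
               as.Date(c("2016-01-01", "2016-01-01", NA, NA, "2016-01-02")))
  expect_equal(attr(a, "n_unassigned"), 2L)
})

test_that("nightly summaries sum sleep and wakes and average efficiency", {
  s <- sessions_df(c("2016-01-01T22:00", "2016-01-02T03:30"),
                   asleep = c(300, 120), inbed = c(round(300 / 0.95), round(120 / 0.85)),
                   wakes = c(2, 1))
  s$efficiency_pct <- c(95, 85)  # exact values for the arithmetic check
  n <- summarize_nights(assign_sessions_to_nights(s))
  expect_equal(nrow(n), 1L)
  expect_equal(n$tst_minutes, 420)
  expect_equal(n$se_pct, 90)
  expect_equal(n$awakenings, 3)
  expect_equal(n$n_sessions, 2L)

  one <- sessions_df("2016-01-01T23:00", asleep = 388, inbed = 419, wakes = 2)
  n1 <- summarize_nights(assign_sessions_to_nights(one))
  expect_equal(n1$tst_minutes, 388)
  expect_equal(n1$se_pct, 100 * 388 / 419)
  expect_equal(n1$awakenings, 2)
})

test_that("clock means wrap midnight and agree with a brute-force oracle", {
  expect_equal(as.character(circular_clock_mean(c("23:00", "01:00"))), "00:00")
  expect_equal(as.character(circular_clock_mean("22:00")), "22:00")
  expect_equal(as.character(circular_clock_mean(c("20:00", "20:00"))), "20:00")
  expect_error(circular_clock_mean(character(0)), "no times")

  # oracle: anchor each time to a concrete date (times before 20:00 fall on
  # the next day), average the POSIX timestamps, read the clock back off
  oracle <- function(t1, t2) {
    anchor <- function(hm) {
      m <- as.integer(substr(hm, 1, 2)) * 60 + as.integer(substr(hm, 4, 5))
      day <- if (m >= 20 * 60) "2016-01-01" else "2016-01-02"
      as.POSIXct(paste(day, hm), tz = "UTC")
    }
    mean_ts <- as.POSIXct(mean(as.numeric(c(anchor(t1), anchor(t2)))),
                          origin = "1970-01-01", tz = "UTC")
    format(round(mean_ts, "mins"), "%H:%M")
  }
  grid <- sprintf("%02d:%02d", c(20:23, 0:7), 0)
  grid <- as.vector(outer(c(20:23, 0:7), seq(0, 50, 10),
                          function(h, m) sprintf("%02d:%02d", h, m)))
  set.seed(1)
  pairs <- cbind(sample(grid, 120, TRUE), sample(grid, 120, TRUE))
  for (i in seq_len(nrow(pairs))) {
    expect_equal(as.character(circular_clock_mean(pairs[i, ])),
                 oracle(pairs[i, 1], pairs[i, 2]),
                 info = paste(pairs[i, ], collapse = " & "))
  }
})

test_that("volunteer summaries average nights; short sessions count for TST only", {
  s <- sessions_df(c("2016-01-01T23:00", "2016-01-02T23:00", "2016-01-04T01:00"),
                   asleep = c(360, 480, 120), inbed = c(360, 480, 120))
  a <- assign_sessions_to_nights(s)
  v <- summarize_volunteer(a)
  # the 2 h session contributes to night 3's TST but not the clock means
  expect_equal(v$n_nights, 3L)
  expect_equal(v$tst_hours, mean(c(360, 480, 120)) / 60)
  expect_equal(v$sleep_hour, "23:00")
  expect_equal(v$wake_hour, "06:00")  # mean of 05:00 and 07:00

  one <- assign_sessions_to_nights(
    sessions_df("2016-01-01T23:30", asleep = 420, inbed = 420))
  v1 <- summarize_volunteer(one)
  expect_equal(v1$sleep_hour, "23:30")
  expect_equal(v1$wake_hour, "06:30")
  expect_false(v1$clock_times_missing)

  short <- assign_sessions_to_nights(
    sessions_df("2016-01-01T23:30", asleep = 120, inbed = 120))
  vs <- summarize_volunteer(short)
  expect_true(vs$clock_times_missing)
  expect_true(is.na(vs$sleep_hour))
  expect_equal(vs$tst_hours, 2)
})

test_that("nightly TST conserves assigned sleep minutes and naps never enter", {
  b <- generate_cohort(sim_config(n_volunteers = 30, seed = 9, nap_rate = 0.5))
  a <- assign_sessions_to_nights(b$sessions)
  nights <- summarize_nights(a)
  expect_equal(sum(nights$tst_minutes),
               sum(a$minutes_asleep[!is.na(a$night_of)]))
  expect_lt(sum(nights$tst_minutes), sum(a$minutes_asleep))  # naps exist, excluded
})

test_that("volunteer SE is normalized: all-perfect efficiency gives exactly 100", {
  b <- generate_cohort(sim_config(n_volunteers = 10, seed = 3))
  s <- b$sessions
  s$efficiency_pct <- 100
  summ <- derive_sleep_summary(s, days = NULL)
  expect_true(all(summ$se_pct == 100))
  summ2 <- derive_sleep_summary(b$sessions, b$days)
  expect_true(all(summ2$se_pct >= 0 & summ2$se_pct <= 100))
})

test_that("night gating keeps a night only when its start day is complete", {
  s <- sessions_df(c("2016-01-01T23:00", "2016-01-02T23:00", "2016-01-03T23:00",
                     "2016-01-04T23:00"), asleep = c(400, 200, 400, 400))
  d <- days_df(hr = c(23, 10, 23, 23), steps = c(1, 1, 1, 1))
  summ <- derive_sleep_summary(s, d)
  expect_equal(summ$n_nights, 3L)  # the short night on the incomplete day dropped
  expect_equal(summ$tst_hours, 400 / 60)
})
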