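# Synthetic cohort generator. Emulates a wearable-tracked population cohort:
# nightly sleep sessions with realistic clock times spanning midnight,
# occasional naps and incomplete tracker days, PSQI responses that are
# noisier and coarser than true sleep, CVD markers with gender-specific
# distributions, and telomere length with planted age and sleep-duration
# effects plus batch structure. Every planted parameter is echoed in a
# ground-truth table so each pipeline stage can be validated end to end.
#
# All randomness flows from one seed through deterministic per-volunteer
# substreams, so adding a volunteer never perturbs the others.

# gender-specific marker distributions (mean, sd) for the simulated cohort
.marker_params <- list(
  bmi = list(Female = c(22.83, 3.80), Male = c(24.27, 3.06)),
  wc = list(Female = c(79.01, 11.08), Male = c(86.82, 9.36)),
  whtr = list(Female = c(0.50, 0.07), Male = c(0.51, 0.05)),
  bfp = list(Female = c(33.16, 7.65), Male = c(23.64, 6.48)),
  smp = list(Female = c(35.49, 4.40), Male = c(42.57, 4.25)),
  sbp = list(Female = c(122.54, 17.53), Male = c(132.06, 15.04)),
  dbp = list(Female = c(73.82, 12.85), Male = c(82.40, 10.88)),
  total_chol = list(Female = c(5.38, 0.93), Male = c(5.39, 0.97)),
  ldl = list(Female = c(3.34, 0.81), Male = c(3.45, 0.91)),
  hdl = list(Female = c(1.58, 0.32), Male = c(1.36, 0.32)),
  tg = list(Female = c(1.02, 0.54), Male = c(1.33, 0.80)),
  fbg = list(Female = c(5.18, 0.50), Male = c(5.39, 0.73)),
  resting_hr = list(Female = c(69.79, 6.37), Male = c(68.23, 6.48))
)

#' Simulation configuration
#'
#' Builds a validated configuration for [generate_cohort()] /
#' [generate_cohort_table()]. Defaults describe the emulated study
#' population: a mean nightly sleep of 388 min (6 h 28 min) with sleep
#' efficiency 92.584\% (SD 3.060), about 4 tracked nights per volunteer
#' (range 3-11), a predominantly Chinese cohort (91.1/3.5/3.3/2.1\%
#' Chinese/Indian/Malay/Others), 54.36\% female, ages 21-69, and planted
#' effects on sleep duration (males -16 min, alcohol +19 min, Malay -41,
#' Indian +32, manual occupation -27, age -0.493 min/yr) and telomere
#' length (-259 bp at 40-60 y and -432 bp at 60-80 y vs 20-40 y; +356 bp
#' for adequate [> 7 h] vs insufficient [< 5 h] sleepers). Self-reported
#' sleep is the true duration plus a +6 min bias and heavy recall noise,
#' rounded to half hours.
#'
#' @param n_volunteers Cohort size (default 482).
#' @param seed Master seed; a fixed seed yields byte-identical output.
#' @param null_effects When TRUE, zero every planted effect and remove
#'   marker gender differences, giving a fully null cohort for type-I-error
#'   calibration.
#' @param ... Overrides for any default listed below (unknown names are an
#'   error): \code{tst_mean_minutes}, \code{tst_between_sd},
#'   \code{tst_within_sd}, \code{se_mean_pct}, \code{se_between_sd},
#'   \code{se_within_sd}, \code{nap_rate}, \code{missing_day_rate},
#'   \code{split_night_rate}, \code{start_mean_clock},
#'   \code{start_sd_minutes}, \code{awakenings_lambda},
#'   \code{selfreport_bias_minutes}, \code{selfreport_noise_sd_minutes},
#'   \code{selfreport_rounding_hours}, \code{effects} (named list),
#'   \code{ethnicity_probs}, \code{prob_female}, \code{prob_alcohol},
#'   \code{prob_manual}, \code{prob_private_residence}, \code{age_mean},
#'   \code{age_sd}, \code{age_range}, \code{ltl_base_bp}, \code{ltl_sd_bp},
#'   \code{ltl_batch_shift_bp}, \code{n_seq_runs}, \code{ts_per_bp},
#'   \code{marker_tst_slope}.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_volunteers = 482, seed = 1, null_effects = FALSE, ...) {
  cfg <- list(
    n_volunteers = n_volunteers,
    seed = seed,
    nights_min = 3, nights_max = 11, nights_extra_lambda = 1,
    tst_mean_minutes = 388, tst_between_sd = 55, tst_within_sd = 40,
    se_mean_pct = 92.584, se_between_sd = 3.060, se_within_sd = 1.0,
    nap_rate = 0.10, missing_day_rate = 0.12, split_night_rate = 0.20,
    start_mean_clock = "23:30", start_sd_minutes = 45,
    awakenings_lambda = 2,
    selfreport_bias_minutes = 6, selfreport_noise_sd_minutes = 200,
    selfreport_rounding_hours = 0.5,
    effects = list(
      gender_tst_minutes = -16,       # male vs female
      alcohol_tst_minutes = 19,
      malay_tst_minutes = -41,
      indian_tst_minutes = 32,
      manual_occupation_tst_minutes = -27,
      age_tst_minutes_per_year = -0.493,
      ltl_sleepgroup_bp = 356,        # adequate (>7 h) vs insufficient (<5 h)
      age_ltl_bp_40_60 = -259,
      age_ltl_bp_60_80 = -432
    ),
    ethnicity_probs = c(Chinese = 0.911, Indian = 0.035, Malay = 0.033, Others = 0.021),
    prob_female = 0.5436,
    prob_alcohol = 0.45,
    prob_manual = 0.15,
    prob_private_residence = 0.25,
    age_mean = 46, age_sd = 12, age_range = c(21, 69),
    ltl_base_bp = 4700, ltl_sd_bp = 430, ltl_batch_shift_bp = 150, n_seq_runs = 2,
    ts_per_bp = 7.1e-4,
    marker_tst_slope = 0,             # null marker-TST association by default
    marker_gender_effects = TRUE,
    study_start = as.Date("2016-03-01")
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) stop("unknown sim_config field '", unknown[1L], "'")
  if (!is.null(over$effects)) {
    bad <- setdiff(names(over$effects), names(cfg$effects))
    if (length(bad) > 0L) stop("unknown effect '", bad[1L], "'")
    cfg$effects[names(over$effects)] <- over$effects
    over$effects <- NULL
  }
  cfg[names(over)] <- over
  if (null_effects) {
    cfg$effects[] <- lapply(cfg$effects, function(x) 0)
    cfg$marker_gender_effects <- FALSE
    cfg$marker_tst_slope <- 0
    cfg$ltl_batch_shift_bp <- 0
  }
  rates <- c(cfg$nap_rate, cfg$missing_day_rate, cfg$split_night_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  sds <- c(cfg$tst_between_sd, cfg$tst_within_sd, cfg$se_between_sd,
           cfg$se_within_sd, cfg$selfreport_noise_sd_minutes, cfg$ltl_sd_bp)
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  if (abs(sum(cfg$ethnicity_probs) - 1) > 1e-8) stop("ethnicity_probs must sum to 1")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  n =", x$n_volunteers, ", seed =", x$seed, "\n")
  cat("  TST:", x$tst_mean_minutes, "min (between-SD", x$tst_between_sd,
      ", within-SD", x$tst_within_sd, ")\n")
  cat("  SE:", x$se_mean_pct, "% (SD", x$se_between_sd, ")\n")
  cat("  planted effects:",
      paste(names(x$effects), unlist(x$effects), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# volunteer-level draws: demographics, planted true sleep parameters
.draw_volunteers <- function(cfg) {
  n <- cfg$n_volunteers
  eff <- cfg$effects
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.substream_seed(cfg$seed, i, stream = 1L))
    gender <- if (stats::runif(1) < cfg$prob_female) "Female" else "Male"
    ethnicity <- sample(names(cfg$ethnicity_probs), 1L, prob = cfg$ethnicity_probs)
    age <- round(min(max(stats::rnorm(1, cfg$age_mean, cfg$age_sd),
                         cfg$age_range[1]), cfg$age_range[2]))
    alcohol <- if (stats::runif(1) < cfg$prob_alcohol) "Yes" else "No"
    occupation <- sample(c("Manual-labor", "Service", "Office", "Unemployed-retired"),
                         1L, prob = c(cfg$prob_manual, 0.20, 0.45,
                                      1 - cfg$prob_manual - 0.65))
    residence <- if (stats::runif(1) < cfg$prob_private_residence) "Private" else
      "Public-housing"
    smoking <- sample(c("Ex-smoker", "Never", "Current"), 1L, prob = c(0.15, 0.70, 0.15))
    exercise <- sample(c("Never/hardly", "Occasional", "Regular"), 1L,
                       prob = c(0.35, 0.40, 0.25))
    caffeine <- sample(c("No", "Yes"), 1L, prob = c(0.3, 0.7))
    n_nights <- min(cfg$nights_min + stats::rpois(1, cfg$nights_extra_lambda),
                    cfg$nights_max)
    # planted linear structure on true nightly sleep duration; the baseline
    # is centred so the cohort mean equals tst_mean_minutes in expectation
    exp_offset <- (1 - cfg$prob_female) * eff$gender_tst_minutes +
      cfg$prob_alcohol * eff$alcohol_tst_minutes +
      cfg$ethnicity_probs[["Malay"]] * eff$malay_tst_minutes +
      cfg$ethnicity_probs[["Indian"]] * eff$indian_tst_minutes +
      cfg$prob_manual * eff$manual_occupation_tst_minutes
    tst_mu <- cfg$tst_mean_minutes - exp_offset +
      (gender == "Male") * eff$gender_tst_minutes +
      (alcohol == "Yes") * eff$alcohol_tst_minutes +
      (ethnicity == "Malay") * eff$malay_tst_minutes +
      (ethnicity == "Indian") * eff$indian_tst_minutes +
      (occupation == "Manual-labor") * eff$manual_occupation_tst_minutes +
      (age - cfg$age_mean) * eff$age_tst_minutes_per_year +
      stats::rnorm(1, 0, cfg$tst_between_sd)
    tst_mu <- max(tst_mu, 120)
    se_mu <- min(max(cfg$se_mean_pct + stats::rnorm(1, 0, cfg$se_between_sd), 55), 99.5)
    rows[[i]] <- data.frame(
      volunteer_id = sprintf("V%04d", i), idx = i,
      gender = gender, ethnicity = ethnicity, age = age,
      alcohol = alcohol, occupation = occupation, residence_type = residence,
      smoking = smoking, exercise = exercise, caffeine = caffeine,
      n_nights = n_nights, tst_mu = tst_mu, se_mu = se_mu,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# markers, steps and LTL given per-volunteer observed/true sleep
.draw_phenotypes <- function(vol, cfg, tst_hours_obs) {
  n <- nrow(vol)
  eff <- cfg$effects
  out <- vol[, c("volunteer_id", "gender", "ethnicity", "age", "alcohol",
                 "occupation", "residence_type", "smoking", "exercise",
                 "caffeine"), drop = FALSE]
  tst_centred <- tst_hours_obs - cfg$tst_mean_minutes / 60
  for (i in seq_len(n)) {
    set.seed(.substream_seed(cfg$seed, vol$idx[i], stream = 4L))
    g <- if (cfg$marker_gender_effects) vol$gender[i] else "pooled"
    for (mk in names(.marker_params)) {
      p <- .marker_params[[mk]]
      ms <- if (g == "pooled") {
        c(mean(c(p$Female[1], p$Male[1])), mean(c(p$Female[2], p$Male[2])))
      } else p[[g]]
      out[[mk]][i] <- stats::rnorm(1, ms[1], ms[2]) +
        cfg$marker_tst_slope * tst_centred[i]
    }
    out$avg_daily_steps[i] <- max(500, stats::rnorm(
      1, if (g == "Male") 11061 else 10350, if (g == "Male") 3819 else 3466))
    # telomere length: age-group and sleep-duration-group effects, in bp
    age_eff <- if (vol$age[i] > 60) eff$age_ltl_bp_60_80 else
      if (vol$age[i] > 40) eff$age_ltl_bp_40_60 else 0
    sleep_eff <- if (tst_hours_obs[i] > 7) 0 else
      if (tst_hours_obs[i] < 5) -eff$ltl_sleepgroup_bp else -eff$ltl_sleepgroup_bp / 2
    ltl_true <- cfg$ltl_base_bp + age_eff + sleep_eff +
      stats::rnorm(1, 0, cfg$ltl_sd_bp)
    run <- sample(paste0("run", seq_len(cfg$n_seq_runs)), 1L)
    shift <- (match(run, paste0("run", seq_len(cfg$n_seq_runs))) - 1) *
      cfg$ltl_batch_shift_bp
    out$ltl_true_bp[i] <- ltl_true
    out$seq_run[i] <- run
    out$ltl_wgs_bp[i] <- ltl_true + shift
    out$ltl_qpcr_ts[i] <- cfg$ts_per_bp * ltl_true
  }
  out
}

#' Generate a volunteer-level cohort table
#'
#' Fast path of the simulator: draws the cohort directly at the volunteer
#' level (no raw session JSON), with observed wearable TST equal to the true
#' volunteer mean plus night-sampling noise
#' (\code{tst_within_sd / sqrt(n_nights)}). Suitable for statistical
#' calibration experiments (type-I error, CI coverage) where the raw-file
#' plumbing is irrelevant.
#'
#' @param config A [sim_config()].
#' @return Cohort data frame with demographics, sleep metrics, self-report,
#'   CVD markers, steps and LTL columns (\code{ltl_wgs_bp} carries the
#'   sequencing-run shift; \code{ltl_true_bp} does not).
#' @export
generate_cohort_table <- function(config = sim_config()) {
  cfg <- config
  vol <- .draw_volunteers(cfg)
  n <- nrow(vol)
  tst_obs <- numeric(n); se_obs <- numeric(n); awak_obs <- numeric(n)
  sr_hours <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(.substream_seed(cfg$seed, vol$idx[i], stream = 2L))
    k <- vol$n_nights[i]
    tst_obs[i] <- vol$tst_mu[i] + stats::rnorm(1, 0, cfg$tst_within_sd / sqrt(k))
    se_obs[i] <- min(vol$se_mu[i] + stats::rnorm(1, 0, cfg$se_within_sd / sqrt(k)), 100)
    awak_obs[i] <- mean(stats::rpois(k, cfg$awakenings_lambda))
    sr <- vol$tst_mu[i] + cfg$selfreport_bias_minutes +
      stats::rnorm(1, 0, cfg$selfreport_noise_sd_minutes)
    sr_hours[i] <- .round_to(max(sr, 60) / 60, cfg$selfreport_rounding_hours)
  }
  ph <- .draw_phenotypes(vol, cfg, tst_obs / 60)
  out <- cbind(
    ph[, c("volunteer_id", "gender", "ethnicity", "age", "alcohol", "occupation",
           "residence_type", "smoking", "exercise", "caffeine")],
    data.frame(n_nights = vol$n_nights,
               tst_hours = tst_obs / 60,
               se_pct = se_obs,
               awakenings = awak_obs,
               selfreport_tst_hours = sr_hours,
               true_tst_minutes = vol$tst_mu,
               stringsAsFactors = FALSE),
    ph[, setdiff(names(ph), c("volunteer_id", "gender", "ethnicity", "age",
                              "alcohol", "occupation", "residence_type",
                              "smoking", "exercise", "caffeine"))]
  )
  rownames(out) <- NULL
  out
}

.round_to <- function(x, unit) round(x / unit) * unit

#' Generate a full synthetic cohort bundle
#'
#' Produces everything the ingestion pipeline reads: per-volunteer sleep
#' sessions (some nights split into two bouts, naps injected outside the
#' night window), tracker-day records with incomplete days, PSQI responses
#' derived from true sleep with bias, noise and half-hour rounding,
#' a phenotype table with CVD markers, steps and telomere length, and a
#' ground-truth table of realized per-volunteer sleep metrics.
#'
#' Ground truth is computed from the generated night-session records
#' themselves (sum of asleep minutes per night, unweighted mean session
#' efficiency per night, then per-volunteer means over all generated
#' nights), independently of the pipeline code paths, so noiseless
#' configurations admit exact recovery checks.
#'
#' @param config A [sim_config()].
#' @return A \code{somno_bundle} list: \code{sessions}, \code{days},
#'   \code{psqi}, \code{phenotypes}, \code{ground_truth}, \code{config}.
#' @export
generate_cohort <- function(config = sim_config()) {
  cfg <- config
  vol <- .draw_volunteers(cfg)
  n <- nrow(vol)
  all_sessions <- vector("list", n)
  all_days <- vector("list", n)
  psqi <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.substream_seed(cfg$seed, vol$idx[i], stream = 3L))
    g <- .generate_volunteer_stream(vol[i, ], cfg)
    all_sessions[[i]] <- g$sessions
    all_days[[i]] <- g$days
    truth[[i]] <- g$truth
    psqi[[i]] <- .generate_psqi_response(vol[i, ], g$truth, cfg)
  }
  truth <- do.call(rbind, truth)
  ph <- .draw_phenotypes(vol, cfg, truth$true_tst_minutes / 60)
  structure(list(
    sessions = do.call(rbind, all_sessions),
    days = do.call(rbind, all_days),
    psqi = do.call(rbind, psqi),
    phenotypes = ph,
    ground_truth = truth,
    config = cfg
  ), class = "somno_bundle")
}

# one volunteer's nightly sessions, naps and tracker days
.generate_volunteer_stream <- function(v, cfg) {
  k <- v$n_nights
  dates <- cfg$study_start + seq_len(k) - 1L
  sess <- list()
  night_tst <- numeric(k); night_se <- numeric(k); night_aw <- numeric(k)
  for (j in seq_len(k)) {
    start_clock <- .parse_clock(cfg$start_mean_clock) +
      stats::rnorm(1, 0, cfg$start_sd_minutes)
    start_clock <- round(min(max(start_clock, 20 * 60), 24 * 60 + 7.5 * 60))
    start_ts <- as.POSIXct(paste(dates[j], "00:00"), tz = "UTC") + start_clock * 60
    tst <- max(60, round(v$tst_mu + stats::rnorm(1, 0, cfg$tst_within_sd)))
    eff <- min(max(v$se_mu + stats::rnorm(1, 0, cfg$se_within_sd), 50), 100)
    wakes <- stats::rpois(1, cfg$awakenings_lambda)
    split <- stats::runif(1) < cfg$split_night_rate && tst >= 300
    if (split) {
      part1 <- round(tst * stats::runif(1, 0.60, 0.75))
      parts <- c(part1, tst - part1)
      gap <- round(stats::runif(1, 10, 40))
      w1 <- min(wakes, stats::rbinom(1, wakes, 0.6))
      wk <- c(w1, wakes - w1)
    } else {
      parts <- tst
      gap <- 0
      wk <- wakes
    }
    cur <- start_ts
    effs <- numeric(length(parts))
    for (p in seq_along(parts)) {
      inbed <- max(parts[p], round(parts[p] * 100 / eff))
      effs[p] <- 100 * parts[p] / inbed
      sess[[length(sess) + 1L]] <- data.frame(
        volunteer_id = v$volunteer_id, start = cur, end = cur + inbed * 60,
        minutes_asleep = parts[p], minutes_in_bed = inbed, wake_count = wk[p],
        efficiency_pct = effs[p], stringsAsFactors = FALSE)
      cur <- cur + (inbed + gap) * 60
    }
    night_tst[j] <- sum(parts)
    night_se[j] <- mean(effs)
    night_aw[j] <- sum(wk)
    # occasional afternoon nap, outside the night window
    if (stats::runif(1) < cfg$nap_rate) {
      nap_start <- as.POSIXct(paste(dates[j], "00:00"), tz = "UTC") +
        round(stats::runif(1, 13 * 60, 16 * 60)) * 60
      nap_len <- round(stats::runif(1, 30, 90))
      nap_bed <- nap_len + round(stats::runif(1, 5, 15))
      sess[[length(sess) + 1L]] <- data.frame(
        volunteer_id = v$volunteer_id, start = nap_start,
        end = nap_start + nap_bed * 60, minutes_asleep = nap_len,
        minutes_in_bed = nap_bed, wake_count = stats::rbinom(1, 1, 0.3),
        efficiency_pct = 100 * nap_len / nap_bed, stringsAsFactors = FALSE)
    }
  }
  complete <- stats::runif(k) >= cfg$missing_day_rate
  hr <- ifelse(complete, stats::runif(k, 20.5, 24), stats::runif(k, 4, 19.5))
  steps <- pmax(0, round(stats::rnorm(k, 10700, 3600)))
  steps[steps == 0] <- 1000
  zero_step_day <- !complete & stats::runif(k) < 0.3
  steps[zero_step_day] <- 0
  hr[zero_step_day] <- stats::runif(sum(zero_step_day), 20.5, 24)
  days <- data.frame(volunteer_id = v$volunteer_id, date = dates,
                     hr_coverage_hours = round(hr, 2), total_steps = steps,
                     stringsAsFactors = FALSE)
  sessions <- do.call(rbind, sess)
  sessions <- sessions[order(sessions$start), , drop = FALSE]
  truth <- data.frame(
    volunteer_id = v$volunteer_id,
    n_nights = k,
    n_days_complete = sum(complete & steps > 0),
    true_tst_minutes = mean(night_tst),
    true_se_pct = mean(night_se),
    true_awakenings = mean(night_aw),
    tst_mu_minutes = v$tst_mu,
    stringsAsFactors = FALSE
  )
  list(sessions = sessions, days = days, truth = truth)
}

# PSQI response as a biased, coarsened transform of true sleep
.generate_psqi_response <- function(v, truth, cfg) {
  set.seed(.substream_seed(cfg$seed, v$idx, stream = 5L))
  sr_min <- truth$true_tst_minutes + cfg$selfreport_bias_minutes +
    stats::rnorm(1, 0, cfg$selfreport_noise_sd_minutes)
  sleep_hours <- .round_to(max(sr_min, 60) / 60, cfg$selfreport_rounding_hours)
  bed_clock <- .round_to(.parse_clock(cfg$start_mean_clock) +
                           stats::rnorm(1, 0, 30), 15) %% 1440
  tib_min <- max(sleep_hours * 60 + round(stats::runif(1, 15, 75)), sleep_hours * 60 + 15)
  rise_clock <- (bed_clock + tib_min) %% 1440
  lam <- truth$true_awakenings
  q5b <- max(0L, min(3L, as.integer(round(lam - 0.8 + stats::rnorm(1, 0, 0.9)))))
  minor <- function(p3) sample(0:3, 1L, prob = c(1 - p3 - 0.12, 0.08, 0.04, p3))
  data.frame(
    volunteer_id = v$volunteer_id,
    bed_time = .fmt_clock(bed_clock),
    rise_time = .fmt_clock(rise_clock),
    sleep_latency_minutes = round(stats::rgamma(1, shape = 2, scale = 8)),
    sleep_hours = sleep_hours,
    q5a = minor(0.02), q5b = q5b, q5c = minor(0.02), q5d = minor(0.01),
    q5e = minor(0.01), q5f = minor(0.01), q5g = minor(0.02), q5h = minor(0.01),
    q5i = minor(0.01), q5j = minor(0.01),
    q6_quality = sample(0:3, 1L, prob = c(0.45, 0.40, 0.12, 0.03)),
    q7_medication = sample(0:3, 1L, prob = c(0.90, 0.05, 0.03, 0.02)),
    q8_drowsy = sample(0:3, 1L, prob = c(0.55, 0.30, 0.12, 0.03)),
    q9_enthusiasm = sample(0:3, 1L, prob = c(0.60, 0.28, 0.09, 0.03)),
    stringsAsFactors = FALSE
  )
}

#' Export the ground-truth table
#'
#' @param bundle A \code{somno_bundle} from [generate_cohort()].
#' @return Per-volunteer realized true sleep metrics with the planted
#'   effect coefficients attached as the \code{"effects"} attribute.
#' @export
export_ground_truth <- function(bundle) {
  stopifnot(inherits(bundle, "somno_bundle"))
  out <- bundle$ground_truth
  attr(out, "effects") <- bundle$config$effects
  out
}

#' Write a cohort bundle to disk
#'
#' Emits the same file dialects the ingestion functions read: one
#' \code{<id>.sleep.json} and \code{<id>.days.json} per volunteer, plus
#' \code{psqi.csv}, \code{phenotypes.csv} and \code{ground_truth.csv}.
#'
#' @param bundle A \code{somno_bundle}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "somno_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in unique(bundle$sessions$volunteer_id)) {
    s <- bundle$sessions[bundle$sessions$volunteer_id == id, , drop = FALSE]
    writeLines(write_sleep_log(s), file.path(dir, paste0(id, ".sleep.json")))
    d <- bundle$days[bundle$days$volunteer_id == id, , drop = FALSE]
    writeLines(write_day_log(d), file.path(dir, paste0(id, ".days.json")))
  }
  utils::write.csv(bundle$psqi, file.path(dir, "psqi.csv"), row.names = FALSE)
  utils::write.csv(bundle$phenotypes, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  utils::write.csv(export_ground_truth(bundle), file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Simulate qPCR plates consistent with target T/S ratios
#'
#' Builds a long well table for [compute_ts()]: for each batch, a telomere
#' (T) and a single-copy-gene (S) plate carrying the threefold standard
#' dilution series (109.0, 36.3, 12.1, 4.0, 1.3 ng/uL) in triplicate, the
#' shared control sample in triplicate, and each sample in triplicate in
#' identical well positions on the two plates. Plate-level multiplicative
#' shifts emulate run-to-run quantification differences (removed by the
#' interplate normalization); Cq noise is Gaussian on the cycle scale.
#'
#' @param samples Data frame with \code{sample_id}, \code{ts} (target T/S
#'   ratio) and optionally \code{batch}.
#' @param seed RNG seed.
#' @param s_conc Underlying single-copy-gene concentration (ng/uL;
#'   default 35, matching the nominal DNA input so samples sit near the
#'   control on the standard curve).
#' @param control_conc Control sample concentration (default 35 ng/uL, the
#'   nominal value used by [compute_ts()]).
#' @param cq_sd Per-well Cq noise SD in cycles (0 gives exact arithmetic).
#' @param plate_shift_sd SD of log-normal plate-level concentration shifts.
#' @param slope,intercept_t,intercept_s True curve parameters used to
#'   convert concentrations to Cq (default: ideal doubling, slope -3.3219).
#' @return Plate well table for [compute_ts()].
#' @export
generate_qpcr_plates <- function(samples, seed = 1, s_conc = 35,
                                 control_conc = 35, cq_sd = 0.1,
                                 plate_shift_sd = 0.05,
                                 slope = -1 / log10(2), intercept_t = 30,
                                 intercept_s = 28) {
  set.seed(seed)
  if (is.null(samples$batch)) samples$batch <- "batch1"
  std_concs <- c(109.0, 36.3, 12.1, 4.0, 1.3)
  to_cq <- function(conc, intercept) slope * log10(conc) + intercept +
    stats::rnorm(length(conc), 0, cq_sd)
  rows <- list()
  for (b in unique(samples$batch)) {
    sb <- samples[samples$batch == b, , drop = FALSE]
    for (assay in c("T", "S")) {
      pid <- paste0(assay, "_", b)
      intercept <- if (assay == "T") intercept_t else intercept_s
      shift <- exp(stats::rnorm(1, 0, plate_shift_sd))
      std <- data.frame(plate_id = pid, assay = assay,
                        sample_id = paste0("std", rep(seq_along(std_concs), each = 3)),
                        role = "standard", conc = rep(std_concs, each = 3),
                        batch = b, stringsAsFactors = FALSE)
      std$cq <- to_cq(std$conc, intercept)
      ctrl <- data.frame(plate_id = pid, assay = assay, sample_id = "control",
                         role = "control", conc = NA_real_, batch = b,
                         stringsAsFactors = FALSE)[rep(1, 3), ]
      ctrl$cq <- to_cq(rep(control_conc * shift, 3), intercept)
      true_conc <- if (assay == "T") sb$ts * s_conc else rep(s_conc, nrow(sb))
      smp <- data.frame(plate_id = pid, assay = assay,
                        sample_id = rep(sb$sample_id, each = 3),
                        role = "sample", conc = NA_real_, batch = b,
                        stringsAsFactors = FALSE)
      smp$cq <- to_cq(rep(true_conc * shift, each = 3), intercept)
      rows[[length(rows) + 1L]] <- rbind(std, ctrl, smp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
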