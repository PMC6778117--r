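test_that("configuration is validated and echoes planted parameters", {
  cfg <- sim_config(n_volunteers = 10, seed = 3)
  expect_equal(cfg$tst_mean_minutes, 388)
  expect_equal(cfg$se_mean_pct, 92.584)
  expect_equal(cfg$effects$gender_tst_minutes, -16)
  expect_error(sim_config(nap_rate = 1.5), "rates")
  expect_error(sim_config(tst_between_sd = -1), "non-negative")
  expect_error(sim_config(nonsense = 1), "unknown sim_config field")
  expect_error(sim_config(effects = list(bogus = 1)), "unknown effect")
  null <- sim_config(null_effects = TRUE)
  expect_true(all(unlist(null$effects) == 0))
})

test_that("a fixed seed reproduces the bundle exactly", {
  b1 <- generate_cohort(sim_config(n_volunteers = 8, seed = 19))
  b2 <- generate_cohort(sim_config(n_volunteers = 8, seed = 19))
  expect_identical(b1$sessions, b2$sessions)
  expect_identical(b1$days, b2$days)
  expect_identical(b1$psqi, b2$psqi)
  expect_identical(b1$phenotypes, b2$phenotypes)
  b3 <- generate_cohort(sim_config(n_volunteers = 8, seed = 20))
  expect_false(identical(b1$sessions, b3$sessions))
})

test_that("adding a volunteer does not perturb existing volunteers' draws", {
  b8 <- generate_cohort(sim_config(n_volunteers = 8, seed = 19))
  b9 <- generate_cohort(sim_config(n_volunteers = 9, seed = 19))
  first8 <- b9$sessions[b9$sessions$volunteer_id %in%
                          unique(b8$sessions$volunteer_id), , drop = FALSE]
  expect_equal(first8, b8$sessions, ignore_attr = TRUE)
})

test_that("ground truth covers every volunteer and matches the configuration", {
  cfg <- sim_config(n_volunteers = 150, seed = 6)
  b <- generate_cohort(cfg)
  gt <- export_ground_truth(b)
  expect_setequal(gt$volunteer_id, unique(b$sessions$volunteer_id))
  expect_setequal(gt$volunteer_id, b$phenotypes$volunteer_id)
  expect_equal(attr(gt, "effects"), cfg$effects)
  # cohort mean of realized true TST near the configured mean (3 SE band)
  se_mean <- sd(gt$true_tst_minutes) / sqrt(nrow(gt))
  expect_lt(abs(mean(gt$true_tst_minutes) - cfg$tst_mean_minutes), 3 * se_mean + 5)
  expect_true(all(gt$n_nights >= 3 & gt$n_nights <= 11))
})

test_that("the derivation pipeline recovers truth within simulated noise", {
  b <- generate_cohort(sim_config(n_volunteers = 80, seed = 14))
  summ <- derive_sleep_summary(b$sessions, b$days)
  m <- merge(summ, export_ground_truth(b))
  expect_gt(cor(m$tst_hours * 60, m$true_tst_minutes), 0.95)
  expect_gt(cor(m$se_pct, m$true_se_pct), 0.9)
  expect_gt(cor(m$awakenings, m$true_awakenings), 0.9)
})

test_that("volunteer exclusion matches the missing-day process analytically", {
  cfg <- sim_config(n_volunteers = 400, seed = 23)
  b <- generate_cohort(cfg)
  qc <- qc_cohort(b$days)
  p_complete <- 1 - cfg$missing_day_rate
  k <- cfg$nights_min + 0:(cfg$nights_max - cfg$nights_min)
  pk <- dpois(k - cfg$nights_min, cfg$nights_extra_lambda)
  pk[length(pk)] <- pk[length(pk)] + 1 - sum(pk)  # truncation mass at the top
  p_excl <- sum(pk * pbinom(2, k, p_complete))
  obs <- mean(!qc$included)
  tol <- 3 * sqrt(p_excl * (1 - p_excl) / nrow(qc))
  expect_lt(abs(obs - p_excl), tol + 0.01)
})

test_that("planted demographic effects are identifiable from one default cohort", {
  tab <- generate_cohort_table(sim_config(n_volunteers = 500, seed = 31))
  fit <- fit_linear_model("demo", tab,
                          formula = tst_hours ~ age + gender + ethnicity +
                            alcohol + occupation)
  beta <- function(term) fit$beta[fit$term == term] * 60
  expect_lt(beta("genderMale"), 0)
  expect_gt(beta("alcoholYes"), 0)
  expect_lt(beta("ethnicityMalay"), 0)
  expect_gt(beta("ethnicityIndian"), 0)
  # magnitudes in the right vicinity (minutes)
  expect_lt(abs(beta("genderMale") - (-16)), 15)
  expect_lt(abs(beta("alcoholYes") - 19), 15)
})

test_that("self-report emulates coarse, biased recall of true sleep", {
  tab <- generate_cohort_table(sim_config(n_volunteers = 500, seed = 32))
  expect_true(all((tab$selfreport_tst_hours * 60) %% 30 == 0))  # half-hour grid
  r <- correlate(tab$tst_hours, tab$selfreport_tst_hours, "spearman")
  expect_gt(r$r, 0.1)
  expect_lt(r$r, 0.5)
})
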