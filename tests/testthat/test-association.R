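test_that("correlation follows the Spearman/Pearson conventions", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  self <- correlate(x, x, "pearson")
  expect_equal(self$r, 1)
  expect_equal(self$n, 10L)
  mono <- correlate(exp(x), x, "spearman")
  expect_equal(mono$r, 1)
  expect_lt(correlate(exp(x), x, "pearson")$r, 1)
  expect_equal(correlate(x, -x, "pearson")$r, -1)
  expect_error(correlate(rep(1, 10), x), "constant")
  expect_error(correlate(1:2, 2:1), "at least 3")
})

test_that("a planted effect is recovered in the near-noiseless limit", {
  set.seed(1)
  n <- 200
  d <- data.frame(tst_hours = runif(n, 4, 9), age = runif(n, 21, 69),
                  gender = sample(c("Female", "Male"), n, TRUE),
                  ethnicity = sample(c("Chinese", "Indian", "Malay", "Others"),
                                     n, TRUE),
                  avg_daily_steps = runif(n, 4000, 18000))
  d$bmi <- 2 * d$tst_hours + rnorm(n, 0, 1e-8)
  r <- fit_linear_model("marker_m1", d, marker = "bmi")
  tst <- r[r$term == "tst_hours", ]
  expect_equal(tst$beta, 2, tolerance = 1e-6)
  expect_lt(tst$p, 1e-10)
  expect_true(all(r$ci_low <= r$beta & r$beta <= r$ci_high))
  expect_equal(tst$n, n)
})

test_that("coefficients match the closed-form normal-equations solution", {
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(15:50, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    d <- data.frame(y, X)
    f <- stats::as.formula(paste("y ~", paste(colnames(X), collapse = " + ")))
    got <- fit_linear_model("adhoc", d, formula = f)
    want <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))[, 1]
    expect_equal(got$beta, unname(want), tolerance = 1e-8)
  }
})

test_that("degenerate designs are rejected with informative errors", {
  d <- data.frame(y = rnorm(30), a = rnorm(30))
  d$b <- d$a
  expect_error(fit_linear_model("dup", d, formula = y ~ a + b), "collinear")
  d2 <- data.frame(y = rnorm(30), gender = factor(rep("Female", 30),
                                                  levels = c("Female", "Male")))
  expect_error(fit_linear_model("empty", d2, formula = y ~ gender),
               "no observations")
  expect_error(fit_linear_model("missing", d2, formula = y ~ nosuchcol),
               "missing required column")
})

test_that("relabelling factor levels while keeping the reference leaves betas unchanged", {
  set.seed(3)
  n <- 150
  d <- data.frame(y = rnorm(n), age = runif(n, 20, 70),
                  gender = sample(c("Female", "Male"), n, TRUE))
  r1 <- fit_linear_model("m", d, formula = y ~ age + gender)
  d2 <- d
  d2$gender <- factor(ifelse(d$gender == "Female", "W", "M"), levels = c("M", "W"))
  r2 <- fit_linear_model("m", d2, formula = y ~ age + gender,
                         refs = c(gender = "W"))
  expect_equal(r2$beta, r1$beta)
  expect_equal(r2$p, r1$p)
})

test_that("group comparisons use t and chi-squared tests as appropriate", {
  x <- rnorm(40)
  same <- compare_groups(c(x, x), rep(c("a", "b"), each = 40))
  expect_equal(unname(diff(same$means)), 0)
  expect_gt(same$p, 0.99)
  paired <- compare_groups(x, y = x + 0.5, paired = TRUE)
  expect_equal(paired$means, -0.5)
  cat1 <- sample(c("u", "v"), 200, TRUE)
  chi <- compare_groups(factor(cat1), y = factor(sample(c("p", "q"), 200, TRUE)))
  expect_equal(chi$method, "chi-squared")
  expect_true(chi$p >= 0 && chi$p <= 1)
  expect_error(compare_groups(rnorm(3), c("a", "b", "b")), "at least 2")
})

test_that("TST categories follow the <5 h / >7 h / >9 h cuts with adequate as reference", {
  b <- categorize_tst(c(4.9, 8.0, 6.0, 5.0, 7.0), "binary")
  expect_equal(as.character(b), c("insufficient", "adequate", NA, NA, NA))
  expect_equal(levels(b)[1], "adequate")
  t3 <- categorize_tst(c(4.9, 8.0, 9.0, 9.5, 6.0), "three_level")
  expect_equal(as.character(t3), c("insufficient", "adequate", "adequate", "long", NA))
  expect_equal(levels(t3), c("adequate", "insufficient", "long"))
})

test_that("the battery is deterministic and degrades gracefully without LTL", {
  tab <- generate_cohort_table(sim_config(n_volunteers = 150, seed = 4))
  tab$ltl_wgs_bp <- batch_adjust(tab$ltl_wgs_bp, tab$seq_run)
  r1 <- run_battery(tab)
  r2 <- run_battery(tab)
  expect_identical(r1, r2)
  expect_true(all(c("model_id", "term", "beta", "ci_low", "ci_high", "p", "n")
                  %in% names(r1)))
  expect_true(all(r1$p >= 0 & r1$p <= 1))
  expect_true(all(r1$ci_low <= r1$beta & r1$beta <= r1$ci_high))

  no_ltl <- tab[, setdiff(names(tab), c("ltl_wgs_bp", "ltl_qpcr_ts"))]
  expect_warning(r3 <- run_battery(no_ltl), "LTL")
  expect_false(any(grepl("^ltl", r3$model_id)))
  expect_true(any(grepl("^marker_m1", r3$model_id)))
  expect_error(run_battery(tab, markers = "nosuch"), "missing required column")
})
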