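# Covariate-adjusted association battery. All linear models are ordinary
# least squares fitted as Gaussian GLMs (glm, family = gaussian), with
# per-term Wald 95% confidence intervals and two-sided p-values. p-values
# are reported unadjusted for multiplicity.

#' Reference levels for cohort factors
#'
#' The registered factor reference levels used throughout the battery:
#' Female for gender; Chinese for ethnicity; Public-housing for residence
#' type; Others for education; Manual-labor for occupation; No for alcohol,
#' caffeine, tea and green-tea consumption; Ex-smoker for smoking;
#' Never/hardly for exercise.
#'
#' @return Named character vector mapping column name to reference level.
#' @export
somno_reference_levels <- function() {
  c(gender = "Female",
    ethnicity = "Chinese",
    residence_type = "Public-housing",
    education = "Others",
    occupation = "Manual-labor",
    alcohol = "No",
    caffeine = "No",
    tea = "No",
    green_tea = "No",
    smoking = "Ex-smoker",
    exercise = "Never/hardly",
    sleep_group = "adequate")
}

#' Apply registered reference levels to a cohort table
#'
#' Converts the listed columns to factors (when present) and releases them
#' against their registered reference level.
#'
#' @param data Cohort data frame.
#' @param refs Named vector of reference levels, see
#'   [somno_reference_levels()].
#' @return The data frame with releveled factors.
#' @export
set_reference_levels <- function(data, refs = somno_reference_levels()) {
  for (col in intersect(names(refs), names(data))) {
    f <- data[[col]]
    if (!is.factor(f)) f <- factor(f)  # keep declared levels of real factors
    if (!refs[[col]] %in% levels(f)) {
      stop("reference level '", refs[[col]], "' absent from column '", col, "'")
    }
    data[[col]] <- stats::relevel(f, ref = refs[[col]])
  }
  data
}

#' Registered model presets
#'
#' Formula templates for the analysis battery; \code{\{marker\}},
#' \code{\{factor\}} and \code{\{ltl\}} are substituted at fit time.
#' Cohort-table column names: \code{age} (years), \code{gender},
#' \code{ethnicity}, \code{avg_daily_steps}, \code{tst_hours},
#' \code{se_pct}, \code{bmi}, \code{sleep_group} and the marker / LTL
#' columns.
#'
#' @return Named character vector of formula templates.
#' @export
model_presets <- function() {
  c(marker_m1 = "{marker} ~ age + gender + ethnicity + avg_daily_steps + tst_hours",
    marker_m2 = "{marker} ~ age + gender + ethnicity + avg_daily_steps + se_pct",
    marker_m3 = "{marker} ~ age + gender + ethnicity + avg_daily_steps + tst_hours + se_pct",
    tst_socio = "tst_hours ~ age + gender + ethnicity + {factor}",
    ltl_tst = "{ltl} ~ age + gender + ethnicity + bmi + tst_hours",
    ltl_group = "{ltl} ~ age + gender + ethnicity + bmi + sleep_group",
    ltl_inter_age = "{ltl} ~ tst_hours * age + gender + ethnicity + bmi",
    ltl_inter_gender = "{ltl} ~ tst_hours * gender + age + ethnicity + bmi")
}

.build_formula <- function(preset, marker = NULL, factor = NULL, ltl = NULL) {
  tmpl <- model_presets()[[preset]]
  if (is.null(tmpl)) stop("unknown model preset '", preset, "'")
  subst <- c(marker = marker, factor = factor, ltl = ltl)
  for (key in names(subst)) {
    tmpl <- gsub(paste0("\\{", key, "\\}"), subst[[key]], tmpl)
  }
  if (grepl("\\{", tmpl)) stop("preset '", preset, "' needs a substitution: ", tmpl)
  stats::as.formula(tmpl)
}

#' Fit one association model
#'
#' Fits an ordinary least-squares model (Gaussian GLM) for one registered
#' preset or an explicit formula, with listwise deletion of incomplete rows,
#' and returns one row per term with the Wald 95\% CI
#' (\eqn{\hat\beta \pm z_{0.975}\,\mathrm{SE}}) and two-sided p-value.
#'
#' @param model_id Label carried into the results (also the preset name when
#'   \code{formula} is \code{NULL}).
#' @param data Cohort data frame; factors are releveled via
#'   [set_reference_levels()] before fitting.
#' @param formula Explicit model formula; when \code{NULL}, \code{model_id}
#'   must name a preset from [model_presets()].
#' @param marker,socio_factor,ltl Substitutions for preset templates.
#' @param refs Reference levels.
#' @return Data frame of association results: \code{model_id}, \code{term},
#'   \code{beta}, \code{ci_low}, \code{ci_high}, \code{p}, \code{n}.
#'   Rank-deficient designs and factors with empty levels are errors.
#' @export
fit_linear_model <- function(model_id, data, formula = NULL, marker = NULL,
                             socio_factor = NULL, ltl = NULL,
                             refs = somno_reference_levels()) {
  if (is.null(formula)) {
    formula <- .build_formula(model_id, marker = marker, factor = socio_factor, ltl = ltl)
  }
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0L) stop("missing required column '", miss[1L], "'")
  data <- set_reference_levels(data[, vars, drop = FALSE], refs = refs)
  for (v in vars) {
    if (is.factor(data[[v]])) {
      empty <- levels(data[[v]])[tabulate(data[[v]], nbins = nlevels(data[[v]])) == 0L]
      if (length(empty) > 0L) {
        stop("factor '", v, "' has level(s) with no observations: ",
             paste(empty, collapse = ", "))
      }
    }
  }
  data <- data[stats::complete.cases(data), , drop = FALSE]
  # levels emptied by listwise deletion are dropped, as in standard practice
  data <- droplevels(data)
  fit <- stats::glm(formula, data = data, family = stats::gaussian())
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(0.975)
  out <- data.frame(
    model_id = model_id,
    term = rownames(sm),
    beta = sm[, "Estimate"],
    ci_low = sm[, "Estimate"] - z * sm[, "Std. Error"],
    ci_high = sm[, "Estimate"] + z * sm[, "Std. Error"],
    p = sm[, 4L],
    n = nrow(data),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Correlation with the study's method conventions
#'
#' Spearman rank correlation for continuous-vs-ordinal pairs (questionnaire
#' scores), Pearson for continuous-vs-continuous pairs; two-sided p-values;
#' pairwise-complete observations.
#'
#' @param x,y Numeric vectors.
#' @param method \code{"spearman"} or \code{"pearson"}.
#' @return Data frame with \code{method}, \code{r}, \code{p}, \code{n}.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector")
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  data.frame(method = method, r = unname(ct$estimate), p = ct$p.value,
             n = length(x), stringsAsFactors = FALSE)
}

#' Group comparisons
#'
#' Two-sided Student's t-test for a continuous outcome across two groups
#' (unpaired) or between paired vectors; chi-squared test for two
#' categorical vectors.
#'
#' @param values Numeric outcome vector, or a categorical vector when
#'   \code{y} is also categorical.
#' @param grouping Two-level grouping factor (unpaired comparison).
#' @param y Second vector: paired numeric values when \code{paired = TRUE},
#'   or a categorical vector for the chi-squared test.
#' @param paired Paired t-test when \code{TRUE}.
#' @return List with \code{method}, group \code{means} (or mean difference
#'   for paired data), and \code{p}.
#' @export
compare_groups <- function(values, grouping = NULL, y = NULL, paired = FALSE) {
  if (!is.null(y) && (is.factor(values) || is.character(values))) {
    tab <- table(values, y)
    ht <- stats::chisq.test(tab)
    return(list(method = "chi-squared", means = NULL, p = ht$p.value))
  }
  if (paired) {
    if (is.null(y)) stop("paired comparison needs y")
    ok <- stats::complete.cases(values, y)
    if (sum(ok) < 2L) stop("need at least 2 complete pairs")
    d <- values[ok] - y[ok]
    # an (effectively) constant difference has no within-pair variance; the
    # mean difference is exact and the t statistic undefined
    p <- if (stats::sd(d) <= sqrt(.Machine$double.eps) * max(abs(d), 1)) NA_real_ else
      stats::t.test(values[ok], y[ok], paired = TRUE)$p.value
    return(list(method = "paired t", means = mean(d), p = p))
  }
  g <- factor(grouping)
  if (nlevels(g) != 2L) stop("grouping must have exactly 2 levels")
  ns <- table(g[!is.na(values)])
  if (any(ns < 2L)) stop("each group needs at least 2 observations")
  ht <- stats::t.test(values ~ g)
  list(method = "Welch t", means = tapply(values, g, mean, na.rm = TRUE), p = ht$p.value)
}

#' Categorize wearable TST into sleep-duration groups
#'
#' \code{binary}: insufficient (< 5 h) vs adequate (> 7 h), with the middle
#' excluded from the contrast (\code{NA}). \code{three_level}: insufficient
#' (< 5 h), adequate (> 7 and \eqn{\le} 9 h, the reference level) and long
#' (> 9 h); 5-7 h remains excluded.
#'
#' @param tst_hours Numeric TST in hours.
#' @param scheme \code{"binary"} or \code{"three_level"}.
#' @return Factor with \code{"adequate"} as the first (reference) level.
#' @export
categorize_tst <- function(tst_hours, scheme = c("binary", "three_level")) {
  scheme <- match.arg(scheme)
  out <- rep(NA_character_, length(tst_hours))
  out[tst_hours < 5] <- "insufficient"
  if (scheme == "binary") {
    out[tst_hours > 7] <- "adequate"
    factor(out, levels = c("adequate", "insufficient"))
  } else {
    out[tst_hours > 7 & tst_hours <= 9] <- "adequate"
    out[tst_hours > 9] <- "long"
    factor(out, levels = c("adequate", "insufficient", "long"))
  }
}

#' Run the full association battery
#'
#' Fits the marker models (1: TST, 2: SE, 3: TST + SE) for every CVD risk
#' marker, the socioeconomic/lifestyle models for TST, and the LTL models
#' (continuous TST, sleep-duration group contrast and the age/gender
#' interaction models) for every LTL column present. Returns one tidy row
#' per model term, deterministically ordered; rerunning on the same input
#' yields identical output.
#'
#' @param cohort Merged cohort table (sleep summaries, PSQI, phenotypes,
#'   LTL).
#' @param markers Marker column names (defaults to those present among the
#'   standard CVD markers).
#' @param socio_factors Socioeconomic/lifestyle factor column names present
#'   in the table.
#' @param ltl_vars LTL column names; models are skipped with a warning when
#'   none is present.
#' @param alpha Significance threshold used only to set the
#'   \code{significant} flag (default 0.05; p-values are unadjusted).
#' @return Data frame of association results with a \code{significant}
#'   logical column.
#' @export
run_battery <- function(cohort,
                        markers = NULL,
                        socio_factors = NULL,
                        ltl_vars = c("ltl_wgs_bp", "ltl_qpcr_ts"),
                        alpha = 0.05) {
  std_markers <- c("bmi", "wc", "whtr", "bfp", "smp", "sbp", "dbp",
                   "total_chol", "ldl", "hdl", "tg", "fbg", "resting_hr")
  if (is.null(markers)) markers <- intersect(std_markers, names(cohort))
  miss <- setdiff(markers, names(cohort))
  if (length(miss) > 0L) stop("missing required column '", miss[1L], "'")
  if (is.null(socio_factors)) {
    socio_factors <- intersect(c("residence_type", "education", "occupation",
                                 "income", "alcohol", "smoking", "exercise",
                                 "caffeine"), names(cohort))
  }
  res <- list()
  for (mk in markers) {
    for (preset in c("marker_m1", "marker_m2", "marker_m3")) {
      res[[length(res) + 1L]] <- fit_linear_model(
        paste(preset, mk, sep = ":"), cohort,
        formula = .build_formula(preset, marker = mk))
    }
  }
  for (sf in socio_factors) {
    res[[length(res) + 1L]] <- fit_linear_model(
      paste("tst_socio", sf, sep = ":"), cohort,
      formula = .build_formula("tst_socio", factor = sf))
  }
  ltl_present <- intersect(ltl_vars, names(cohort))
  if (length(ltl_present) == 0L && length(ltl_vars) > 0L) {
    warning("no LTL column present; skipping LTL models")
  }
  for (lv in ltl_present) {
    cohort$sleep_group <- categorize_tst(cohort$tst_hours, "binary")
    for (preset in c("ltl_tst", "ltl_group", "ltl_inter_age", "ltl_inter_gender")) {
      res[[length(res) + 1L]] <- fit_linear_model(
        paste(preset, lv, sep = ":"), cohort,
        formula = .build_formula(preset, ltl = lv))
    }
  }
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
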