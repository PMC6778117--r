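---
title: "Methods: wearable sleep metrics, questionnaire concordance and sleep-phenotype associations"
author: "somnocohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable sleep metrics, questionnaire concordance and sleep-phenotype associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnocohort)
```

# Scope

somnocohort implements a digital-phenotyping analysis pipeline for
population cohorts tracked with consumer wearables: ingestion of
Fitbit-style JSON sleep and activity logs, day-completeness quality
control, derivation of per-volunteer sleep metrics, scoring of the
Pittsburgh Sleep Quality Index (PSQI), a covariate-adjusted linear-model
battery against cardiovascular-risk markers and leukocyte telomere length
(LTL), qPCR T/S-ratio telomere arithmetic, and a synthetic-cohort
generator with planted effects that makes every stage testable without
any participant data.

# Sleep-metric derivation

## Day completeness and volunteer inclusion

Consumer wearables are worn intermittently, so a completeness filter
precedes any sleep summary. A tracker day is *data-complete* when it has
at least 20 h of intraday heart-rate coverage and a nonzero step count;
a volunteer is included when at least three days are complete. Both
thresholds are arguments (`min_hours`, `min_complete_days`) with these
defaults. Coverage hours are consumed precomputed from the day log;
deriving them from raw heart-rate samples is out of scope.

A night is gated by the completeness of its **start** calendar day: the
night of day *D* is retained iff day *D* is complete. Gating on the end
day, or on both, would be equally defensible; the start-day rule is the
simplest convention consistent with keying sessions by start time, and it
is what `derive_sleep_summary()` applies.

An optional percentile filter on mean daily steps
(`flag_step_outliers()`) is available for removing extreme-activity
outliers but is off by default: where to draw the line is a study-level
choice, so the package refuses to hard-code one.

## The night window

A sleep session belongs to the night of day *D* when its start time falls
in the half-open window [20:00 of *D*, 08:00 of *D*+1). Sessions starting
between 08:00 and 20:00 are naps: they are counted and reported but never
enter nightly totals. The half-open convention makes membership
unambiguous at the boundaries — a session starting exactly at 20:00 is in,
one starting exactly at 08:00 is out — and guarantees a session belongs to
at most one night. Window bounds are arguments for sensitivity analyses.

## Nightly and volunteer-level aggregation

For each night: total sleep time (TST) is the *sum* of assigned sessions'
asleep minutes; sleep efficiency (SE) is the *unweighted mean* of their
efficiencies (each recomputed as 100 x asleep / in-bed minutes, never
trusted from the file); awakenings are the sum of wake counts. Weighting
nightly SE by session length would be a reasonable alternative; the
unweighted mean treats each sleep bout as one observation of the
sleeper's efficiency and is the convention implemented.

Volunteer-level metrics are plain means over retained nights: TST in
hours, SE in percent, awakenings per night. No reweighting by the number
of nights is applied.

## Sleep and wake clock times

Averaging clock times that straddle midnight is ill-defined on the raw
0-24 h scale (23:00 and 01:00 must average to 00:00, not 12:00).
`circular_clock_mean()` maps each time to minutes elapsed since a window
origin (20:00 by default), takes the arithmetic mean, and maps back. For
times constrained to one 24-h cycle after the origin — always true of
night-window sleep onsets and their wake times — this is exact, not an
approximation.

Sleep hour averages the start times of window-assigned sessions with
duration of at least 3 h; wake hour averages the end times of *those same
sessions*. Applying the 3-h filter to wake hour as well keeps the two
clock summaries describing the same set of principal sleep bouts; the
filter threshold (180 min) and its basis (in-bed minutes by default,
since a tracker session is a bed interval; asleep minutes optionally) are
arguments.

# PSQI scoring

The 19 self-rated items yield seven component scores of 0-3 and a global
score of 0-21 (`score_psqi()`); the five bed-partner items are not part
of the scored instrument. Band edges for the two components that interact
with wearable metrics are centralized in `psqi_bands()`:

* component 3 (duration): > 7 h scores 0, (6, 7] scores 1, [5, 6] scores
  2, < 5 h scores 3. The printed instrument categories ("6-7", "5-6")
  abut at their endpoints; the edges implemented resolve the ties
  downward (exactly 6 h scores 2, exactly 5 h scores 2), following the
  instrument's usual convention.
* component 4 (habitual SE = self-reported sleep hours over bed-to-rise
  time, wrapping midnight): > 85% scores 0, [75, 85] scores 1, [65, 75)
  scores 2, < 65% scores 3.

Missing items are an error naming the item; the instrument has no
imputation rule and the package does not invent one.

# Association battery

All models are ordinary least squares fitted as Gaussian GLMs
(`stats::glm`), matching the convention of fitting marker associations
with a generalized linear model under a Gaussian error distribution.
Registered presets (`model_presets()`) cover the marker models
(marker ~ age + gender + ethnicity + daily steps + TST and/or SE), the
socioeconomic/lifestyle models (TST ~ age + gender + ethnicity + factor),
the LTL models (LTL ~ age + gender + ethnicity + BMI + TST or
sleep-duration group) and the TST-by-age and TST-by-gender interaction
models. Factor reference levels are registered in
`somno_reference_levels()` (Female; Chinese; Public-housing; Others for
education; Manual-labor; "No" for alcohol/caffeine/tea; Ex-smoker;
Never/hardly) and applied before every fit.

Confidence intervals are Wald intervals, estimate ± z(0.975) x SE, and
p-values are the fit's two-sided t-based p-values. Wald intervals on a
Gaussian GLM differ negligibly from profile or t-quantile intervals at
cohort sample sizes but are stated explicitly so small discrepancies
against other software are explainable. Incomplete rows are deleted
listwise per model and the n actually fitted is reported per term.

No multiple-testing adjustment is applied anywhere: the battery reports
raw p-values with a `significant` flag at 0.05. With ~40 models in a full
battery this is a real limitation — users wanting family-wise control
should feed the output to `p.adjust`.

Degenerate inputs are errors, not silent repairs: rank-deficient designs
name the collinear terms; factors carrying declared levels with no
observations are rejected (levels emptied only by listwise deletion are
dropped, as is standard); correlations of constant vectors are refused. A
paired comparison of vectors with a constant difference reports the exact
mean difference with an `NA` p-value, since the t statistic is undefined
without within-pair variance.

TST enters marker models in hours. For sleep-duration contrasts,
`categorize_tst()` implements insufficient (< 5 h) vs adequate (> 7 h),
optionally splitting adequate (7, 9] from long (> 9 h), with "adequate"
as the reference level and the 5-7 h middle excluded from contrasts.

# Telomere arithmetic

## qPCR T/S ratios

`compute_ts()` implements the relative telomere-length arithmetic: a
per-plate standard curve Cq = slope x log10(conc) + intercept fitted to a
threefold dilution series (109.0, 36.3, 12.1, 4.0, 1.3 ng/uL by
default), interpolation of sample and control wells, triplicate collapse,
interplate normalization from a shared control sample, optional batch
adjustment of the telomere (T) and single-copy-gene (S, *36B4*)
concentrations, and finally T/S. Amplification efficiency is
10^(-1/slope) - 1; an ideal doubling assay has slope -3.3219.

Triplicate handling: the single well farthest from the triplicate median
is dropped if it deviates by more than 0.5 Cq; if the concentration CV of
the remaining wells still exceeds 15%, the sample is flagged for repeat.
Both thresholds are arguments. This is a common laboratory rule; any
outlier policy here is a judgment call, so the policy is explicit and
configurable rather than buried.

Normalization reference: each plate's concentrations are multiplied by
(reference control concentration) / (that plate's mean control
concentration). The reference defaults to the control's *nominal*
concentration (35 ng/uL, the standardized DNA input). A data-independent
reference makes normalization exactly scale-equivariant — rescaling every
well of one plate leaves every T/S ratio unchanged — which is the property
that makes inter-plate shifts harmless. The alternative
`reference = "grand_mean"` anchors the scale to the control's observed
grand mean across plates instead; it averages out control-well noise in
the cohort mean but transmits any one plate's rescaling into the overall
scale. Since T/S is a relative measure, the choice affects only the
scale, never ratios between samples.

## Batch and sequencing-run correction

`batch_adjust()` regresses values on the batch indicator and returns
residuals plus the grand mean: batch main effects are removed exactly
(to numerical tolerance) and the overall mean is preserved. The same
operation serves qPCR experimental batches (applied to T and S
concentrations before the final ratio) and sequencing-run correction of
WGS-based LTL estimates, which the package consumes as precomputed
base-pair values — estimating LTL from reads is an external tool's job.

# The synthetic cohort generator

`generate_cohort()` emulates the study population the pipeline is
designed for: 482 volunteers (54.36% female; 91.1/3.5/3.3/2.1%
Chinese/Indian/Malay/Others; ages 21-69 centred at 46), each with 3-11
tracked nights (mode ~4), nightly sleep around a volunteer-specific mean
(cohort mean 388 min, between-volunteer SD 55 min, within-volunteer SD
40 min), session efficiency around 92.584% (SD 3.060), Poisson(2) wake
counts, sleep onsets near 23:30 spanning midnight, 20% of nights split
into two bouts, afternoon naps on 10% of days, and 12% incomplete
tracker days. Planted, configurable effects on sleep duration: males
-16 min, alcohol +19 min, Malay -41 min, Indian +32 min, manual
occupation -27 min, age -0.493 min/yr. LTL is generated in base pairs
with age-group effects (-259 bp at 40-60 y, -432 bp at 60-80 y vs
20-40 y), a +356 bp advantage of adequate (> 7 h) over insufficient
(< 5 h) sleepers (half that effect for the 5-7 h middle, for
continuity), a sequencing-run shift, and a proportional T/S-scale twin
(7.1e-4 T/S per bp, which maps the 356 bp group effect to 0.253 T/S
units). CVD markers are drawn from gender-specific distributions with a
configurable (default zero) TST slope, so the marker battery is null
unless an effect is requested.

Self-reported sleep is true sleep plus a +6 min bias and Normal recall
noise (SD 200 min), rounded to half hours. The heavy noise is
deliberate: it reproduces the weak-concordance regime in which wearable
and self-reported TST correlate at roughly 0.3 (Spearman), which is what
field comparisons of objective and questionnaire sleep measures find.

Ground truth is computed from the generated night-session records
themselves, independently of the pipeline code paths, so a noiseless
configuration (all SDs and rates zero) admits *exact* recovery checks.
All randomness flows from one master seed through deterministic
per-volunteer substreams: a fixed seed reproduces the bundle
byte-for-byte, and adding a volunteer never perturbs existing ones.

What the generator does **not** emulate: intra-night sleep architecture
(stages, heart-rate dynamics), device-specific wake-detection error
structure, correlated missingness (wear gaps are independent across
days), seasonal or weekday effects, and any marker-marker correlation
beyond shared gender. Passing tests therefore demonstrate that the
pipeline's arithmetic and inference are correct under the stated
generative model, not that the device measurements themselves are
accurate.

`generate_cohort_table()` is a fast volunteer-level path (no raw session
JSON) for statistical calibration experiments; observed TST there is the
true volunteer mean plus night-sampling noise (within-SD / sqrt(nights)).

# Validation experiments and problem sizes

The test suite validates, among others:

* exact recovery of planted TST/SE/awakenings in the noiseless limit
  (100 volunteers, full JSON round trip);
* agreement of every fitted coefficient with the closed-form
  normal-equations solution to 1e-8 (50 random small designs);
* type-I error of the marker battery on fully null cohorts: the
  proportion of terms with p < 0.05 over 200 cohorts of 500 volunteers,
  required to lie in 0.05 ± 0.015;
* 95% CI coverage of the planted gender (-16 min), alcohol (+19 min) and
  sleep-group LTL (356 bp) effects across 500 simulated cohorts of 500
  volunteers, required to lie in 93-97%;
* exact removal of planted batch shifts and exact scale-equivariance of
  plate normalization;
* unbiasedness of T/S recovery under per-well Cq noise (SD 0.1 cycles) on
  the quantified wells, to within 1% over 200 samples. Noise on shared
  wells (standards, control) produces plate-level variance rather than
  bias, so it is assessed separately from the bias check.

These sizes keep the full suite under ten minutes while leaving the
binomial tolerances meaningful.

# Known limitations

* Timestamps are naive local clock times; cohorts spanning timezones or
  daylight-saving transitions need pre-normalized inputs.
* The JSON dialect is a documented minimal subset of consumer-wearable
  sleep payloads, not a faithful clone of any vendor schema version.
* Nightly SE is unweighted across sessions; volunteers with many short
  bouts are summarized differently than under time-weighting.
* Raw p-values throughout; multiplicity control is the user's
  responsibility.
* The LTL-vs-TST slope is reported per hour of TST in the units of the
  LTL column supplied (bp or T/S); the package carries units in the
  result metadata rather than assuming a conversion.
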