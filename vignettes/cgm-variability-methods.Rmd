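---
title: "Methods: glycemic variability analysis for CGM cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycemic variability analysis for CGM cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`cgmgv` implements a cohort-scale analysis pipeline for continuous glucose
monitoring (CGM) data of the kind donated by users of open-source automated
insulin delivery (AID) systems: messy per-individual "entries" files
(timestamp string + sensor glucose in mg/dL), plus a partial self-reported
demographics survey. The pipeline is: simulate (optional) → clean → GV
metrics → cohort analyses → calendar profiles. Because the real donated
dataset is available only on request, the package ships a synthetic cohort
generator with exact ground truth; every downstream stage is tested against
that ground truth.

## Cleaning model

Raw timestamps arrive in four dialects: ISO 8601 with `T`/`Z` markers,
plain `YYYY-MM-DD HH:MM:SS`, day-of-week-prefixed strings, and strings
suffixed with a timezone abbreviation. All are normalised to timezone-naive
wall-clock date-times. Zone markers are recognised against a fixed
abbreviation table and dropped: hour-of-day analyses are behavioural and
local, and per-row zone ground truth is unrecoverable from these files.
Unknown abbreviations and otherwise unparseable strings are counted and
dropped — a batch pipeline cannot hand-repair individual rows, so it
reports them instead.

Value rules, applied in order, each with an audit counter:

* rows whose value is the text `"null"` are dropped;
* non-finite / non-numeric values (`inf`, `NaN`) are dropped;
* values `< 39` mg/dL are device error codes and dropped;
* values `> 1000` mg/dL are dropped;
* values in `(400, 1000]` are replaced by 400, the sensor ceiling.

A value of exactly 1000 sits between two stated rules; we clamp it rather
than drop it, because removal is the more destructive action and is
reserved for values strictly above 1000. No interpolation is performed.
Files of one individual are merged, stably sorted by timestamp, and
de-duplicated keeping the first row per duplicate timestamp (duplicates are
identical timestamps at second resolution; values are not compared).
De-duplication runs after the per-individual merge, so overlapping files
cannot double-count. The whole cleaning pass is idempotent, and
`rows_out = rows_in − Σ removals` holds exactly.

## Glycemic variability metrics

All per-individual statistics are *interday*: computed over the pooled
reading series. Conventions that differ between software stacks are fixed
as follows and exposed as parameters where meaningful:

* quartiles: linear interpolation between order statistics
  (`stats::quantile` type 7);
* SD: sample SD (n − 1 denominator); CV = 100·SD/mean (%);
* TIR: share of readings in the inclusive range [70, 180] mg/dL; the two
  TOR shares are strict (`< 70`, `> 180`), so TIR + TOR<70 + TOR>180 = 100
  exactly;
* POR: share of readings outside mean ± k·SD; the SD multiple k is a free
  parameter (default 1, which gives ~29–32% on near-normal data);
* J-index: `0.001 (mean + SD)^2`;
* GMI: `3.31 + 0.02392 · mean` (% HbA1c-equivalent);
* LBGI/HBGI: with `f(g) = 1.509((ln g)^1.084 − 5.381)` and risk `10 f(g)^2`,
  LBGI is the mean risk over readings with `f < 0` (zero contribution
  otherwise), HBGI symmetrically for `f > 0`. The transform's root is at
  ≈112.5 mg/dL. The constants are the published values of the risk-index
  and GMI methodologies and live in `risk_transform_params()` / the `gmi()`
  arguments rather than as magic numbers;
* rate of change: `(g_i − g_{i−1})/Δt` in mg/dL per minute for consecutive
  pairs with `Δt ≤ max_gap` (default 30 min). Longer gaps are sensor
  outages; skipping them avoids spurious near-zero slopes. `roc_sd` is the
  SD of these rates.

Every metric is checked against an independent brute-force implementation
(naive loops) to 1e-9 on thousands of small random series.

## The synthetic cohort generator

The generator is a first-class module, not a fixture. Per individual, clean
glucose is

> true mean + circadian sinusoid + within-day excursions + AR(1) residual,

clipped to the sensor range [40, 400] and rounded.

* **Circadian sinusoid** — amplitude 20 mg/dL by default, minimum at the
  *centre* of the nadir clock hour (default 8). Published cohort profiles
  report the nadir value but not the peak, so the amplitude is a realism
  choice. Centring the minimum inside the nadir hour makes that hour the
  unique lowest hour-of-day bucket in expectation; a minimum at the bucket
  *boundary* would leave the two adjacent buckets exactly tied.
* **Within-day excursions** — harmonics of the day (periods 24/k h,
  k = 1..3) with fresh Gaussian coefficients each day, exactly mean-zero
  over every day. This is the meal-scale structure of real traces. It
  carries 70% of the residual variance by default, and it is what
  reconciles two otherwise contradictory facts about CGM data: consecutive
  5-minute readings change slowly (cohort ROC SD ≈ 1.4–2.3 mg/dL/min), yet
  a few months of data pin an individual's mean to a couple of mg/dL. A
  single AR(1) cannot do both — the product of its ROC SD and its
  day-to-day mean variability is invariant in the AR timescale — whereas
  day-mean-zero intraday structure contributes variance without slowing
  the convergence of the individual's mean.
* **AR(1) residual** — coefficient 0.95 per 5-minute lag (per-step
  coefficient `0.95^(interval/5)`, so the process timescale is independent
  of the sampling interval). Its innovation SD is modulated by a circadian
  factor (maximum at 23:00, default ±10%) and a seasonal factor (smooth
  cosine over the year, 15% lower at the mid-summer trough), both
  RMS-normalised so the marginal SD stays at the individual's true SD.
* **Between-individual spread** — true means N(139, 30) truncated to
  [70, 250] (+4 mg/dL for females by default); true SDs lognormal around
  49.8 (sdlog 0.2). The published per-individual mean-glucose quartiles
  imply an even wider spread (IQR ≈ 63 mg/dL); we deliberately stay
  narrower to keep tails physiologic.
* **Mess injection** — after clipping, so every raw value < 39 or > 400 is
  attributable to injection. Per-row corruption categories (null text,
  duplicated timestamp, device error code < 39, spike in (420, 1200],
  alternative timestamp dialect) are mutually exclusive, and a duplicated
  row is always an uncorrupted copy; this makes the injected counts match
  the cleaning audit counters *exactly*, which the tests assert.
* **Demographics** — (weight, total daily insulin, daily basal insulin)
  from a Gaussian copula with Spearman targets (0.63, 0.61, 0.69) and
  lognormal marginals; gender 50 male / 28 female / 44 unreported by
  default; per-field missingness mirrors the survey's missing-report
  counts. Basal is not constrained below total insulin — the copula
  reproduces rank dependence, not accounting identities.

What the generator does **not** emulate: meal/bolus event timing,
sensor-compression artifacts, drift between sensor sessions, the
right-skew of real glucose marginals (the process is Gaussian before
clipping, which understates TIR at a given mean/SD relative to real
cohorts), or menstrual-cycle periodicity. Passing recovery tests therefore
demonstrates the correctness of the pipeline's bookkeeping and statistics,
not that the generator is a faithful physiological simulator.

Identifiability note: clipping at the sensor floor biases the *process* SD
downward for individuals whose true mean is within ~1.3 SD of 40 mg/dL.
The ground truth therefore records both the process parameters and the
realized clean-series moments; recovery of the process parameters is
asserted at the cohort's stated parameters (mean 139, SD 49.8), recovery
of the clean moments everywhere.

## Cohort analyses

* **Correlations** — pairwise-complete Spearman with two-sided p-values
  (`stats::cor.test`), no imputation, raw p-values with the number of
  tests reported (mirroring the source analyses, which did not adjust).
* **Min–max normalisation** — per column over the pooled table *before*
  any gender split, so between-stratum ordering of monotone summaries is
  preserved.
* **Gender stratification** — per-stratum n, range, mean, quartiles,
  skewness sign, and a Shapiro–Wilk normality flag at α = 0.05
  (`stats::shapiro.test`, valid for 3 ≤ n ≤ 5000).
* **Clustering** — each individual is represented by their z-scored
  GV-metric vector (mean, SD, CV, TIR, TOR×2, LBGI, HBGI, J-index, GMI,
  ROC SD). This representation is length-invariant across individuals with
  unequal recording durations; an hour-of-day profile vector is a
  reasonable alternative and can be passed via the `features` argument.
  Distance is Euclidean; linkage defaults to Ward (`ward.D2`), the
  standard pairing with Euclidean feature vectors, configurable to
  single/complete/average. "No distinct clusters" is operationalised as:
  no successive merge-height ratio above 2.0 among the top ten merges —
  small early merge heights make ratios lower in the tree meaningless.

## Calendar profiles

Readings are bucketed by wall-clock hour of day (hour h covers
[h:00, h+1:00)), day of week (Mon = 1), day of month, or month. Every
bucket of a granularity is present in the output; empty buckets carry
count 0, single-reading buckets a missing SD, and day-of-month buckets
29–31 simply report their smaller contributing n. Gender-averaged profiles
weight *individuals* equally (mean of per-individual bucket means, and of
bucket SDs): pooled averaging would let an individual with years of data
dominate one with weeks. The pooled mode is available via
`mode = "pooled"` for comparison.

## Problem sizes

Tests and the acceptance script run desk-scale cohorts chosen for
statistical power rather than realism of scale: metric oracles on
thousands of ≤20-reading series; cleaning recovery on 12 individuals ×
200 days of messy 5-minute data; partition identities on 122 individuals ×
2 days; planted-cluster recovery on 20 + 20 individuals × 10 days;
circadian-nadir recovery on 24 + 24 individuals × 600 days at 15-minute
sampling with amplitude 35 mg/dL (sized by an a-priori power simulation of
the hour-bucket argmin); seasonal-SD recovery on 8 individuals × 1 year.
The generator's own defaults describe the full-scale study conditions
(122 individuals, durations lognormal around a 377-day median) and can be
run as such where time allows.

## Known limitations

* Timestamps are treated as local wall-clock; travel across time zones
  within one individual's record will smear their circadian profile.
* The cleaning pipeline drops what it cannot parse; it does not attempt
  the manual repair that a curated analysis might.
* Shapiro–Wilk flags at n near its validity bounds are advisory.
* The slope of basal on total insulin is reported in both regression
  directions by the demographics analysis consumer; the package asserts
  nothing about it, as the published value's direction is ambiguous and a
  component–total regression slope above 1 is internally surprising.
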