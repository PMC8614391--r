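---
title: "Methods: wear-time validation, structural breaks, and period contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wear-time validation, structural breaks, and period contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearbreaks)
```

wearbreaks analyses yearlong cohorts monitored with wrist-worn consumer
activity trackers. The pipeline has four stages: (1) heart-rate-arbitrated
wear-time validation of minute-level device exports, (2) construction of
date-indexed cohort mean series for steps, light physical activity (PA),
moderate-to-vigorous physical activity (MVPA) and sedentary time, (3)
detection and dating of multiple structural breaks in each series, and (4)
quantification of between-period differences with a participant-level
random-intercept model. A synthetic cohort generator with known ground
truth backs every stage's tests. This vignette records the models, the
tunable parameters, and the design decisions.

## Wear-time validation

Consumer wearables report heart rate only while worn, so the count of
calendar minutes with a plausible heart-rate reading is a serviceable wear
proxy. The chain is:

1. **Aphysiologic removal.** Readings outside `[hr_lower, hr_upper]`
   (defaults 50 and 200 bpm) are removed; nonpositive or missing readings
   are malformed input and are dropped with a warning rather than counted
   as aphysiologic.
2. **Wear minutes.** Distinct clock minutes per participant-day containing
   at least one surviving reading; sub-minute duplicates collapse.
3. **Calendar-day sleep.** Device sleep episodes are clipped to the
   half-open day `[00:00, 24:00)` — a minute belongs to the day containing
   its start — so one overnight episode contributes to two days, and a
   calendar day typically accumulates sleep from two adjacent nights.
   Overlapping episodes are unioned, never double-counted.
4. **Day wear.** `day_wear = max(0, wear − sleep)`. Sleep totals are
   subtracted from wear totals rather than intersected minute-by-minute:
   the subtraction-of-totals arithmetic matches the validation rule this
   pipeline implements, and the generator emits heart rate during sleep,
   making the two equivalent on synthetic data. Clipping at zero covers
   the (meaningless) case of more sleep than wear.
5. **Validity.** A day is valid at `day_wear >= 600` minutes; a
   participant is analysed at `>= 250` valid days inside the one-year
   window — 68.5% of the year, a deliberately strict consistency
   requirement.

Timestamps are treated as naive local time throughout; there is no
time-zone or daylight-saving arithmetic (a single-site cohort), and the
internal representation pins them to UTC so that a "minute" is always 60
seconds. A day whose readings are all aphysiologic retains no wear
evidence and yields no assessment row; days present only in the sleep data
are emitted with zero wear and are invalid.

## Cohort series and periods

For each outcome the cohort series is the unweighted mean over valid
participant-days of included participants, one value per date; the
contributing `n` is carried along and dates with fewer than
`min_contributors` (default 1) contributors are dropped. Segmentation runs
on the cohort mean series rather than on pooled participant-days: the
break model below is a model of the population mean level, and the
participant-day dimension is handled separately by the mixed model. A date
with a dropped value simply shortens the observation index; the dynamic
program runs on the index and the dates ride along as labels.

Analysis periods are contiguous, non-overlapping calendar intervals.
The default boundaries are 1 March 2020 and 1 June 2020; because detected
breaks cluster in mid-March and mid-June, the boundary is a configuration
knob rather than a constant, and the acceptance script re-derives the
boundaries from the breaks detected in the step series.

## Structural-break model

Within segment $j$ the series follows a linear regression (by default an
intercept only, i.e. a piecewise-constant mean); breaks are the indices at
which the coefficients change. For a candidate break count $m$ the
partition minimising the total within-segment residual sum of squares
(RSS) subject to a minimum segment length $h = \lceil 0.15\,n \rceil$ is
found **exactly** by dynamic programming over suffix optima; ties go to
the lexicographically earliest break vector. Segment RSS values come from
cumulative cross-product arrays, so each evaluation is $O(1)$.

The number of breaks is selected by
$$\mathrm{BIC}_m = n \log(\mathrm{RSS}_m/n) + k_m \log n, \qquad
k_m = (m+1)p + m,$$
with $p$ regressors per segment; $k_m$ counts the segment coefficients
plus the break positions. The error-variance parameter would add a
constant across $m$ and is omitted. Ties in BIC go to the smaller $m$.
If some $m$ fits exactly (RSS numerically zero) the log is undefined; the
smallest such $m$ is selected and flagged `exact_fit`.

Two numerical points deserve note:

* **RSS monotonicity.** RSS$_{m+1} \le$ RSS$_m$ is guaranteed only while
  the $m$-optimum retains a segment of length $\ge 2h$ that could host an
  extra break. When the minimum-length constraint binds (e.g. $n = 365$,
  $h = 55$, $m = 5$ forces six nearly equal segments), the larger $m$ can
  genuinely fit worse. The package asserts monotonicity exactly where the
  refinement argument applies; constrained non-monotone entries stay in
  the reported table and can never minimise BIC, since they are dominated
  in both terms.
* **Minimum segment fraction.** 0.15 is a conventional default for this
  algorithm class; with yearlong daily data it allows up to five breaks
  and matches regimes roughly 80 days apart. It is configurable via
  `segment_spec()`.

Break-date uncertainty is estimated by a moving-block bootstrap: within
each fitted segment the residuals are resampled in contiguous blocks
(default length 7 days, preserving weekday autocorrelation), added back to
the piecewise fit, and the breaks re-estimated with $m$ fixed at the
selected value; percentile intervals of the replicated break indices are
mapped back to dates. Segments shorter than the block length shrink the
block with a warning. The asymptotic break-date distribution would be an
alternative; the bootstrap was chosen because it is assumption-light and
its coverage is directly testable by simulation (the test suite requires
$\ge 85\%$ empirical coverage at nominal 95% for a 3-sigma step,
$n = 365$, 200 replicates).

## Random-intercept period model

Between-period changes are quantified on participant-day observations
(valid days of included participants):
$$y_{it} = \mu_{\text{period}(t)} + b_i + e_{it}, \qquad
b_i \sim N(0, \sigma_b^2), \quad e_{it} \sim N(0, \sigma^2).$$
The fixed effects are period cell means. Estimation is by restricted
maximum likelihood, profiling both variances out so that only the ratio
$\lambda = \sigma_b^2/\sigma^2$ remains: with a single random intercept,
$(I + \lambda J)^{-1}$ has closed form per participant and every GLS
quantity reduces to per-participant and per-cell sums. The profiled
criterion is minimised by a coarse grid followed by Brent search on
$\log\lambda$, with the $\lambda = 0$ boundary checked explicitly; a
boundary solution (or a single-participant input) is returned flagged with
$\sigma_b^2 = 0$, where the fit provably equals ordinary least squares.
The unit tests verify agreement with an established general mixed-model
implementation to at least five decimals on unbalanced data.

Pairwise period contrasts use the fixed-effect covariance with
normal-approximation intervals; with roughly a hundred participants and
three hundred days each, degrees-of-freedom corrections (Satterthwaite and
kin) would change nothing at the reported precision and are out of scope.
The Bonferroni family is the three pairwise comparisons per outcome
(interval level $1 - \alpha/3$, p-values tripled and capped at 1); no
across-outcome adjustment is applied, matching per-outcome reporting.
Group comparisons (e.g. participants with versus without children) refit
the model with period-by-group cell means and report the within-period
group difference with unadjusted 95% intervals; a group empty in a period
yields a flagged unavailable row.

## The synthetic cohort generator

The generator emulates the study conditions the pipeline is designed for,
with known ground truth:

* **Population trend.** Piecewise levels per outcome with calendar break
  dates 2020-03-13 and 2020-06-13 and reference period levels
  steps (9641, 6769, 7299), light PA (239, 197, 216) min,
  MVPA (47.6, 35.4, 39.9) min, sedentary (659, 712, 678) min.
* **Variance components.** One standardised random intercept per
  participant, scaled per outcome (defaults: 1800 steps, 35/12/70 min),
  plus Gaussian day noise (2500 steps, 50/18/90 min). A shared intercept
  across outcomes is a deliberate simplification: it preserves the
  marginal variance structure each univariate analysis sees.
* **Weekday seasonality.** A fixed Monday–Sunday pattern summing to zero,
  amplitude 5% of the first-segment level, inverted for sedentary time.
  It exists to give the block bootstrap realistic short-range structure.
* **Compliance.** Each regular participant draws a daily compliance
  probability from Beta(2.6, 2.0); about 2.5% of participants never
  achieve a valid day. Compliant days draw a day-wear target from a
  clipped Gaussian (mean 850, SD 90, range 620–1000 min), non-compliant
  days from mean 350, SD 120, range 0–580 min, so the 600-minute boundary
  is never straddled by emission error. These values are calibrated so
  that roughly a third of a 315-participant cohort passes the 250-day
  filter, mirroring the filter cascade the pipeline reports; wear-time
  distributions of real excluded participants are not public, so this is
  calibration, not ground truth. A `dropout_after` switch supports
  testing the filter against mid-year abandonment. Nonwear is
  missing-at-random given the participant's compliance probability.
* **Sleep.** One main episode per night, onset around 23:45 (SD 45 min)
  so most episodes cross midnight, duration 367 (SD 67) min clipped to
  [120, 600]; naps are not modelled because the validation only consumes
  calendar-day totals. Day-wear targets are clamped to the remaining day
  capacity (1440 minus attributed sleep) so minute emission can realise
  them exactly.
* **Minute streams.** All sleep minutes carry a valid reading (the device
  records heart rate during sleep); the day-wear target is placed in
  waking slots; artifact minutes (bpm outside [50, 200]) are added in
  free slots with a binomial count targeting `hr_artifact_rate` (default
  2%) of emitted minutes. Valid readings are Gaussian around 75 bpm —
  there is no circadian heart-rate cycle, no optical-noise physics, and
  no intraday step cadence, so passing tests certify the accounting
  chain, not device realism.

Determinism is part of the contract: a configuration and seed reproduce
byte-identical fixtures, and seeded operations restore the caller's RNG
state.

## Problem sizes used in the tests

The simulation benchmarks run at the sizes the claims refer to: DP
exactness against exhaustive enumeration on 1000 random series with
$n \le 25$, $m \le 3$; BIC selection and bootstrap coverage at $n = 365$
over 100 seeds; REML recovery at 50 participants × 300 days over 50
seeds; and end-to-end break recovery on the default 315-participant
cohort over 50 seeds using the schedule-level wear path (the minute-level
emission is exercised separately at small cohort sizes, where its
equivalence to the schedule is itself a tested contract).

## Known limitations

* The wear proxy cannot distinguish a worn device with failed heart-rate
  sampling from nonwear; days with device-reported steps but no heart
  rate count as nonwear by design.
* Residuals are treated as independent within segments except for what
  the block bootstrap absorbs; an explicitly autocorrelated error model
  is out of scope.
* The mixed model has a single random intercept — no random slopes, no
  serial correlation within participant.
* Figure-grade smoothing is out of scope; `plot_cohort_series()` offers a
  rolling mean for quick inspection only.
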