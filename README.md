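# wearbreaks

Structural-break analysis of yearlong wearable-activity cohorts.

Cohort studies that hand participants a wrist-worn activity tracker for a
year face two linked problems. First, the raw device exports contain long
stretches where the device was not worn, so every participant-day must be
validated before it can be analysed: wearbreaks uses the heart-rate stream
as the wear arbiter (a minute counts as worn if it carries a plausible
reading, 50–200 bpm), subtracts each calendar day's sleep minutes, keeps
days with ≥600 minutes of waking wear, and keeps participants with ≥250
such days in the year. Second, population activity over such a window is
not a smooth trend but a sequence of regimes separated by abrupt changes
(seasons, holidays, public-health orders): wearbreaks detects and dates
those changes and then quantifies the between-regime differences.

The statistical core:

* **BIC/RSS-optimal segmentation.** For each candidate break count
  *m* ≤ m_max, the partition of the daily cohort mean series minimising
  total within-segment RSS (segments ≥ ⌈0.15 n⌉ observations) is found
  exactly by dynamic programming; *m* is selected by
  BIC_m = n·log(RSS_m/n) + [(m+1)p + m]·log n. Break-date uncertainty
  comes from a moving-block bootstrap of within-segment residuals
  (blocks of 7 days, breaks re-estimated per replicate, percentile
  intervals).
* **Random-intercept period model.** On valid participant-days,
  y_it = μ_period(t) + b_i + e_it with b_i ~ N(0, σ_b²),
  e_it ~ N(0, σ²), fitted by profiled REML (one-dimensional Brent search
  over the variance ratio), with Bonferroni-adjusted pairwise period
  contrasts.
* **Synthetic cohort generator.** Minute-level heart-rate streams,
  midnight-spanning sleep episodes, a participant-level compliance model
  and daily outcomes following a known piecewise trend — the ground truth
  every stage is tested against.

## Worked example

Simulate the default synthetic cohort (315 participants, one year,
ground-truth level changes on 2020-03-13 and 2020-06-13), validate wear,
build the step-count series, detect breaks and quantify period changes:

```r
library(wearbreaks)

cfg <- synthetic_config(n_participants = 315, seed = 20191101)
sim <- simulate_cohort(cfg)

assessments <- schedule_to_assessments(sim$schedule)
selection   <- select_participants(assessments)
included    <- selection$participant_id[selection$included]
length(included)
#> [1] 101

series <- build_series(sim$daily, assessments, "steps", included = included)
seg <- select_breaks(series)
seg
#> <segmentation> n = 365, design = constant, h = 55
#>   selected m = 2
#>   breaks at index: 133, 226
#>   break dates: 2020-03-12, 2020-06-13
#>  m       rss      bic
#>  0 609657404 5235.806
#>  1  60868385 4406.579
#>  2  45251187 4310.162
#>  3  45048487 4320.323
#>  4  44868225 4330.659
#>  5  47553131 4363.672

break_intervals(seg, seed = 1)
#>   break_index lo_index hi_index break_date    lo_date    hi_date
#> 1         133      133      133 2020-03-12 2020-03-12 2020-03-12
#> 2         226      221      230 2020-06-13 2020-06-08 2020-06-17

obs <- make_long_observations(sim$daily, assessments, "steps",
  periods = period_definition(boundaries = seg$break_dates + 1),
  included = included)
fit <- fit_random_intercept(obs)
pairwise_contrasts(fit)
#> <contrast table> bonferroni-adjusted, 3 comparison(s), level 0.95
#>   contrast   estimate       se        lo         hi         z        p_adj
#> 1  P2 - P1 -2867.8212 37.70404 -2958.084 -2777.5585 -76.06138 0.000000e+00
#> 2  P3 - P1 -2333.1531 33.75699 -2413.967 -2252.3395 -69.11615 0.000000e+00
#> 3  P3 - P2   534.6682 37.35419   445.243   624.0933  14.31347 5.408599e-46
```

Reading the output: 101 of 315 simulated participants survive the
250-valid-day filter; the segmentation selects two breaks whose dated
positions (last day of the outgoing regime) sit within a day of the
generating truth, with the weaker June shift carrying the wider bootstrap
interval; and the mixed model recovers the generating period levels — a
drop of about 2868 steps/day into the middle period and a partial
rebound of about 535 steps/day after it (truth: 2872 and 530).

The same chain runs from CSV exports on disk (minute heart rate, sleep
episodes, daily summaries) through `run_config()` + `run_pipeline()`,
which also writes per-outcome artifacts and a JSON run report with the
filter cascade counts. A thin command-line wrapper is installed at
`inst/cli/wearbreaks.R` (`simulate`, `run`, `breaks`, `periods`).

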