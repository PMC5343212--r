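---
title: "Costing and cost-effectiveness methods in activecost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing and cost-effectiveness methods in activecost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activecost)
```

`activecost` implements the economic evaluation of a behavioural
physical-activity intervention delivered through a website, as studied in the
Pasos Hacia La Salud randomized trial: a 12-month, two-arm comparison
(104 intervention, 101 control participants) of a Spanish-language,
individually tailored physical-activity program against a wellness
contact-matched control in underactive Latina women. The effect measure is
weekly minutes of moderate-to-vigorous physical activity (MVPA), assessed by
the interviewer-administered 7-day physical activity recall (PAR) and by
hip-worn accelerometer at baseline, 6 months, and 12 months; the economic
question is what a minute of additional MVPA costs the payer under each
delivery arm, and incrementally.

This vignette is the package's account of the methods: the costing rules, the
effectiveness model, the ratio definitions, the deterministic sensitivity and
scaling analyses, the accelerometer scoring rules, and the synthetic-trial
generator — with the numerical conventions and design choices made where the
source material left matters open.

## Micro-costing from the payer perspective

Costs are built bottom-up (the ingredients approach) per arm, including only
what a clinic or community deliverer of the finished program would pay: staff
time for training and delivery, routine website maintenance, hosting,
technical support, materials, and hardware. Research-only activities,
recruitment, and the one-off website development are excluded.

Personnel time is costed at loaded wages. A loaded annual salary (salary plus
fringe benefits) is divided by a 2000-hour work year and rounded to cents —
`hourly_rate()` — then increased by 10% for overhead — `loaded_hourly_rate()`,
carried unrounded. The packaged rate table has a trainer at $86,520/year
($43.26/h, $47.586/h loaded) and a research associate at $56,153/year
($28.08/h, $30.888/h loaded). The loaded annual figures are treated as the
canonical inputs; a separately stated fringe percentage is descriptive only,
because annual figures and their quoted hourly equivalents pin down the work
year exactly while a rounded percentage does not.

Hardware is charged by straight-line depreciation: price × years-used /
depreciation-life, with a 5-year life and 3 years of use as defaults
(`straight_line_depreciation()`), so a $700 computer contributes $420 and a
$400 printer $240.

A `cost_ledger()` stores one row per item with cumulative amounts at the
6-month (intensive-phase) and 12-month horizons, a category, a timing
profile, and a fixed/variable role for the scaling model. Currency is carried
as numeric dollars and rounded half-up to cents only at defined reporting
points; whole-dollar rounding appears only in formatted summaries. Because
published cost tables round every item to whole dollars, recomputed column
totals are documented as matching published ones to within $2.

Two quirks of the packaged reference table deserve note. The control columns
sum to $4901 / $7636 against published totals of $4900 / $7634 — ordinary
item rounding. The 12-month intervention column, however, sums to $14,931
with its $150 video-library row, while the published cumulative total — and
every ratio computed downstream of it — uses $14,781. Rather than silently
dropping the row, the ledger keeps all printed items and
`cost_effectiveness()` accepts *cost overrides*: published arm totals that
replace the ledger sum for specific cells. The same override mechanism serves
the accelerometer gains (below). `pasos_cost_overrides()` carries
$10,712 / $4900 / $14,781 / $7634.

## Effectiveness: interpolated cumulative MVPA gain

Arm-level mean weekly MVPA minutes at weeks 0, 26, and 52 (completers only,
unadjusted) are joined by straight lines, and the cumulative per-person gain
over a window is the area between that piecewise-linear trajectory and the
flat baseline level — a trapezoidal integral in week units
(`cumulative_gain()`). For a single segment this is (Δmean/2) × weeks. The
calendar convention is 26 weeks per 6 months; under it the intervention arm's
PAR trajectory 8.0 → 112.8 → 108.6 min/week yields 1362.4 minutes per person
over 6 months and 4032.6 over 12, and the control arm's 8.5 → 63.5 → 75.9
yields 715 and 2306.2 — exactly the published interpolated totals, which is
why that convention was adopted. Gains are real-valued minutes, rounded only
in reports; `gain_per_month()` divides by window months.

The published *accelerometer* totals (523.0 and 186.3 minutes at 6 months;
1496 and 696 at 12) differ slightly from the trapezoid of the published
rounded means (520.0, 185.9, 1489.8, 720.2); the unrounded means behind them
are unrecoverable. `pasos_gain_overrides()` therefore supplies the published
totals as overrides for ratio work, while the interpolation path remains the
default for any other input. (The 12-month control total is printed once as
695 and once as 696 in the source material; 696 is used, being the value
consistent with the published incremental ratio.)

## Cost-effectiveness ratios

`cost_per_minute()` divides an arm's per-person cost by its per-person minute
gain; `incremental_cost_per_minute()` divides the between-arm cost difference
by the between-arm gain difference. `cost_effectiveness()` assembles the full
grid — both measures, both horizons, per-arm and incremental — computing every
ratio on unrounded per-person costs and unrounded gains and rounding to cents
only in the report table; rounding earlier propagates cent-level errors into
the ratios and does not reproduce the published grid. Zero or equal gains
raise explicit undefined-ratio errors rather than returning infinities, and
negative incremental ratios are flagged as dominance rather than hidden.

On the packaged inputs the fit reproduces every published cell: per-arm PAR
ratios $0.08 / $0.07 at 6 months and $0.04 / $0.03 at 12; accelerometer
$0.20 / $0.26 and $0.10 / $0.11; incremental $0.08 and $0.04 (PAR),
$0.16 and $0.08 (accelerometer).

## One-way sensitivity analysis

`sensitivity_table()` perturbs one input at a time by ±20% (configurable):

* **Staffing costs** scale every personnel-time line item — training,
  delivery, *and* routine website maintenance, in both arms. Maintenance is
  included because it is staff time; with it the published accelerometer
  cells ($0.19 / $0.14 at 6 months) reproduce, and without it they do not.
  When published cost totals are in force as overrides, the staffing delta
  `(m − 1) ×` staffing subtotal is added onto the override so the standard
  row stays anchored.
* **Intervention effectiveness** scales the minute gains in both arms, which
  makes the incremental ratio exactly reciprocal in the multiplier:
  ICER(×m) = ICER/m. This identity is enforced by tests.

Nineteen of the twenty published grid cells reproduce exactly. The twentieth
(effectiveness −20%, accelerometer, 12 months) is printed as $0.12 in the
source table, which contradicts that table's own standard cell: $0.08
standard under the reciprocal identity gives 0.0832/0.8 = $0.10. The package
computes — and its tests assert — $0.10, treating the printed $0.12 as a
typographical error.

## Enrollment scaling

`split_fixed_variable()` divides an arm's ledger into costs that do not grow
with enrollment (hardware, hosting, technical support, training) and costs
that accrue per participant (materials, delivery and maintenance staff time),
the latter calibrated per person at the trial's enrollment (n = 104). The
video library is classed variable, matching its per-person accounting; the
roles are data, so a user can reclassify any row. `scaling_curve()` then
models cost per person per month at enrollment *n* as
(fixed + n × variable) / (n × months): strictly decreasing, bounded below by
the asymptote variable/months (`asymptotic_cost()`). For the 12-month
intervention ledger this gives fixed = $4311 and variable = $102.12/person,
hence $15.69 → 16 at n = 50, $12.10 → 12 at n = 100, $10.31 → 10 at n = 200,
asymptote $8.51. The curve varies the intervention arm's enrollment only,
the reading under which all published curve values reproduce.

## Accelerometer scoring

`mvpa_minutes()` scores minute-level counts with the conventional
vertical-axis moderate-intensity cut point of 1952 counts/min and a 10-minute
minimum bout: a minute counts only when worn, at or above threshold, and
inside a maximal qualifying run of at least the bout length. Bouts are strict
consecutive runs by default; a `max_interruption` knob merges runs separated
by short worn sub-threshold gaps for users who want a tolerance, but defaults
to 0 as the simplest reading of the rule. `wear_valid()` implements the
week-validity rule — ≥10 wear-hours on ≥5 days, or ≥3000 total wear minutes
over ≥4 days with any wear (the second clause's day count is interpreted as
days with nonzero wear). Wear flags are inputs; a ≥60-minute
consecutive-zeros heuristic (`detect_nonwear()`) is available but off by
default, since non-wear detection was not part of the scoring rule being
implemented. The scorer is verified minute-for-minute against a brute-force
run enumeration on a thousand random streams.

## The synthetic trial generator

`simulate_trial()` exists so the whole pipeline can run, and be tested end to
end, without any external data. It emulates the trial's *measured outcome
distributions*, not its behavioural mechanism: per arm and measure, weekly
minutes at weeks 0/26/52 with the published means and SDs (PAR intervention
8.0 (15.0) → 112.8 (97.1) → 108.6 (107.2); control 8.5 (14.6) → 63.5 (88.7) →
75.9 (89.8); accelerometer analogues), 16.1% dropout equal across arms and
independent of outcomes, and baseline eligibility of under 60 self-reported
minutes per week.

Three modelling choices matter:

* **Zero-censored, moment-matched marginals.** Weekly minutes are generated
  as max(0, N(μ*, σ*)) — a point mass of fully inactive weeks plus a
  continuous part, which is how underactive samples look. The latent (μ*, σ*)
  are solved numerically so the *realised* mean and SD equal the configured
  ones. A zero-truncated normal cannot do this job: its coefficient of
  variation is below 1, while the baseline target (mean 8, SD 15) has CV
  1.9; censoring has no such ceiling.
* **Within-person correlation.** Timepoints within a person share a Gaussian
  copula with exchangeable correlation ρ = 0.4, a plausible value for
  repeated physical-activity measures; it is a configuration field, not a
  claim about the trial, which reported none.
* **Eligibility-aware calibration.** The baseline marginal is matched
  conditional on the sub-60 screening rule, and post-baseline latent means
  are shifted by ρ·φ(c)/Φ(c)·σ to undo the selection the screening would
  otherwise propagate through the copula — so completer means recover the
  configured values (verified at n = 5000/arm to within 3 standard errors,
  a run that takes well under a second).

What passing these tests shows is that the analysis pipeline correctly
recovers the parameters of data generated under its own assumptions; it does
not validate normality, the copula, or independence of dropout against real
trial data, none of which the generator can establish.

`simulate_staff_log()` complements this with task-level time entries
(orientation visits, scheduled calls with optional Poisson failed-attempt
minutes, materials preparation, per-cohort training) whose default minutes
are calibrated so the intervention arm's 6-month delivery cost lands within a
few dollars of the published $5674 at the loaded research-associate rate —
reproducing the *structure* of the personnel ledger, with per-seed
variability where attempt distributions are switched on.

## Numerical conventions and degenerate inputs

* Money rounds half-away-from-zero at cent and dollar reporting points;
  internal arithmetic is double precision.
* 6 months = 26 weeks throughout; `gain_per_month()` uses months = weeks ×
  6/26.
* Interpolation refuses extrapolation; windows must be positively oriented
  and inside the observed range.
* Division guards: zero participants, zero-length windows, zero or equal
  gains, and zero enrollment all raise targeted errors naming the quantity.
* Empty ledgers total $0; an all-fixed ledger gives a zero asymptote; a
  zero-variance simulation config reproduces its means exactly.
* Moment matching that cannot succeed (e.g. a configured mean above the
  eligibility ceiling) is a configuration error, not a silent fit.

## Problem sizes used in the test suite

The property suites use 10 random series for the trapezoid-vs-Riemann check
(step 0.001 week), 1000 random streams for the bout scorer, 5000 participants
per arm for parameter recovery, and 10,000 per arm for the dropout checks —
sizes at which Monte-Carlo standard errors are small enough for 3-SE
assertions to be discriminating while the whole suite runs in seconds.

## Limitations

The package evaluates costs against a single effect unit (MVPA minutes); it
does not model health-care costs, QALYs, discounting, or inflation — a
12-month horizon needs none of those, and none were part of the analysis it
implements. The sensitivity machinery is strictly one-way deterministic:
no probabilistic sensitivity analysis or acceptability curves. The
accelerometer scorer operates on count streams, not raw accelerations, and
implements a single vertical-axis cut point.
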